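# culturesim

An agent-based simulation of **cumulative adaptive culture under natural
selection**, for researchers in cultural evolution and human behavioural
ecology who want to dissect how selection pressure, demography and social
connectivity jointly shape a population's cultural repertoire.

Individuals live in groups on a bounded 10×10 grid of renewable resources.
A *cultural trait* is the ability to exploit one of ten resource types, with
an integer skill value 1–10; an individual's trait list is always a prefix
(trait *k* can only follow mastery of trait *k−1*).  The per-step amount an
individual can extract with a trait is

```
rate = b + δ · (v − 1)
```

where `b` is the basic rate at skill 1, `v` the skill value, and `δ` the
**selection differential** — the model's central knob, converting skill into
fitness.  Energy drives everything: a 5-unit metabolic requirement per step,
an energy cap of 50, reproduction only when provisioned (threshold 20, each
parent transfers 10 to the newborn), death on starvation or at age 60.
Individuals that cannot meet the requirement are *under resource pressure*:
only they learn (from parents at birth; obliquely from the group and, in the
*interacting* regime, Moore-neighbouring groups) or invent.  All copying
carries a 5% ±1 error — the source of skill variation; inventing trait
*k+1* requires maximum skill at trait *k* and costs energy.  Pressured
groups fission onto, or migrate to, empty neighbouring squares.  Cumulative
culture is measured as the mean trait-list length; *competition* as the
fraction of the population missing its requirement.

The package provides a compiled simulation engine with tidy accessors,
canned multi-replicate experiment sweeps, and the end-value statistics used
to compare parameter cells: exact (permutation) Wilcoxon rank-sum tests with
Bonferroni correction, and mean ± SD summary tables.

## A worked example

One run in the interacting regime under strong selection:

```r
library(culturesim)

cfg <- sim_config(
  selection_differential = 0.5, resource_level = 50,
  interaction_radius = 2L, n_steps = 300
)
run <- run_sim(cfg, seed = 1)
glance(run)
#> # A tibble: 1 × 8
#>    seed extinct  step population mean_group_size mean_traits competition
#>   <int> <lgl>   <int>      <int>           <dbl>       <dbl>       <dbl>
#> 1     1 FALSE     300       3043            30.4           3       0.357
head(run$events, 4)
#> # A tibble: 2 × 4
#>    step group_id trait_index individual_id
#>   <int>    <int>       <int>         <dbl>
#> 1   181       39           2          1219
#> 2   261       19           3          6088
```

Reading this: after 300 years the grid carries 3043 individuals in 100
groups (mean size 30.4); everyone holds 3 traits — trait 2 was invented in
group 39 at step 181 and trait 3 in group 19 at step 261, each invention
spreading population-wide and unlocking a growth phase (36% of individuals
currently miss their 5-unit requirement, the pressure that drives the next
round of learning).  `tidy(run)` returns the full per-step time series and
`autoplot(run)` plots the population staircase with invention markers.

Multi-cell experiments chain the same way:

```r
sweep <- run_sweep("table1", base_seed = 1, n_runs = 10,
                   resource_levels = c(50, 100))
sweep$summary       # mean ± SD per cell (traits, group size, competition)
sweep$comparisons   # exact rank-sum tests, Bonferroni-corrected
autoplot(sweep)     # cell means with ±1 SD error bars
```

A command-line interface wrapping these functions is installed at
`inst/cli/culturesim` (`culturesim run|sweep|analyze`).

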