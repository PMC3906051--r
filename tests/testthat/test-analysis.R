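test_that("competition and mean traits summarise the living population", {
  cfg <- sim_config()
  groups <- tibble::tibble(id = c(1L, 2L), col = c(0L, 5L), row = c(0L, 5L))
  inds <- flat_inds(4)
  inds$group_id <- c(1L, 1L, 1L, 2L)
  inds$under_pressure <- c(TRUE, FALSE, FALSE, FALSE)
  skills <- rbind(
    skill_row(c(1, 2)), skill_row(c(3, 4, 5, 6)), skill_row(1), skill_row(1)
  )
  s <- make_test_state(cfg, groups, inds, skills)
  expect_equal(competition(s), 0.25)
  expect_equal(mean_traits(s), mean(c(2, 4, 1, 1)))
  # competition equals the group-size-weighted mean of group pressures
  gp <- group_pressure(s)
  expect_equal(competition(s), sum(gp$fraction_unmet * gp$size) / sum(gp$size))
  # invariant under relabeling of individuals
  perm <- c(3L, 1L, 4L, 2L)
  s2 <- s
  s2$individuals <- s$individuals[perm, ]
  s2$skills <- s$skills[perm, ]
  expect_equal(mean_traits(s2), mean_traits(s))
  expect_equal(competition(s2), competition(s))
  # empty population: undefined, reported as missing
  s0 <- s
  s0$individuals <- s$individuals[0, ]
  s0$skills <- s$skills[0, , drop = FALSE]
  expect_true(is.na(competition(s0)))
  expect_true(is.na(mean_traits(s0)))
})

test_that("exact rank-sum p matches published small-sample cases", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 0.1) # 2/20 exact
  # identical samples: maximally central, p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  # complete separation at n = m = 10: 2 / choose(20, 10)
  a <- 30 + seq(0.1, 1, by = 0.1)
  b <- seq(0.1, 1, by = 0.1)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value, 2 / choose(20, 10))
  expect_equal(wilcoxon_rank_sum(a, b)$statistic, 100) # all wins for sample a
})

test_that("exact rank-sum agrees with brute-force enumeration up to n+m=12", {
  set.seed(42)
  cases <- list(
    list(a = c(1.2, 3.4), b = c(2.2, 0.1, 5.5)),
    list(a = rnorm(4), b = rnorm(5)),
    list(a = rnorm(6), b = rnorm(6)),
    list(a = c(1, 2, 2, 3), b = c(2, 3, 3, 4)), # ties -> midranks
    list(a = c(5, 5, 5), b = c(5, 5, 1, 5)),
    list(a = rpois(5, 3), b = rpois(7, 3)) # many ties
  )
  for (cs in cases) {
    expect_equal(
      wilcoxon_rank_sum(cs$a, cs$b)$p_value,
      brute_ranksum_p(cs$a, cs$b),
      info = paste(length(cs$a), length(cs$b))
    )
  }
})

test_that("exact rank-sum matches wilcox.test for untied samples", {
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(6)
    b <- rnorm(8, mean = 0.5)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    w <- wilcoxon_rank_sum(a, b)
    expect_equal(w$p_value, ref$p.value)
    expect_equal(w$statistic, unname(ref$statistic))
  }
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.01, 6), 0.06)
  expect_equal(bonferroni(0.3, 6), 1)
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(c(0.001, 0.5), 4), c(0.004, 1))
})

test_that("sweep summaries report replicate means and sample SD", {
  ev <- tibble::tibble(
    selection_differential = 0.1, resource_level = 50,
    interaction_radius = 1L, innovation_cost = 10, learning_cost = 0,
    mean_traits = c(3, 3, 3), mean_group_size = c(2, 4, 3),
    competition = c(0.1, 0.2, 0.3)
  )
  sm <- summarize_sweep(ev)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$n, 3L)
  expect_equal(sm$mean_traits_mean, 3)
  expect_equal(sm$mean_traits_sd, 0)
  ev2 <- ev[1:2, ]
  ev2$mean_traits <- c(2, 4)
  sm2 <- summarize_sweep(ev2)
  expect_equal(sm2$mean_traits_mean, 3)
  expect_equal(sm2$mean_traits_sd, sqrt(2), tolerance = 1e-12) # 1.414, n-1 SD
})

test_that("pairwise comparisons use the documented correction factors", {
  set.seed(1)
  grid <- tidyr::expand_grid(
    selection_differential = c(0.01, 0.1, 0.5, 1.0),
    resource_level = c(50, 100, 500),
    interaction_radius = c(1L, 2L),
    replicate = 1:4
  )
  grid$mean_traits <- rnorm(nrow(grid), 3)
  grid$mean_group_size <- rnorm(nrow(grid), 20)
  grid$competition <- runif(nrow(grid))
  cmp <- compare_sweep(grid, metrics = "mean_traits")
  # 4 differentials -> 6 pairs; 3 levels -> 3 pairs; 2 regimes -> 1 pair
  expect_setequal(
    unique(cmp$bonferroni_m[cmp$family == "selection_differential"]), 6
  )
  expect_setequal(
    unique(cmp$bonferroni_m[cmp$family == "resource_level"]), 3
  )
  expect_setequal(
    unique(cmp$bonferroni_m[cmp$family == "interaction_regime"]), 1
  )
  expect_equal(cmp$p_corrected, pmin(1, cmp$bonferroni_m * cmp$p_raw))
  expect_true(all(cmp$p_corrected >= cmp$p_raw))
  # family sizes: 6 pairs x 6 fixed cells, 3 x 8, 1 x 12
  expect_equal(sum(cmp$family == "selection_differential"), 36)
  expect_equal(sum(cmp$family == "resource_level"), 24)
  expect_equal(sum(cmp$family == "interaction_regime"), 12)
})
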