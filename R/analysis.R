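# Observables and end-value statistics: competition metric, exact Wilcoxon
# rank-sum tests with Bonferroni correction, and sweep summary tables.

#' Competition level of a population
#'
#' The fraction of living individuals that could not meet their minimum
#' per-step resource requirement (their realised intake fell short of the
#' step requirement).
#'
#' @param state a `sim_state`.
#' @return A proportion in `[0, 1]`, or `NA` for an empty population.
#' @export
competition <- function(state) {
  if (nrow(state$individuals) == 0L) {
    return(NA_real_)
  }
  mean(state$individuals$under_pressure)
}

#' Mean number of cultural traits per individual
#'
#' The arithmetic mean of trait-list lengths over living individuals; the
#' model's measure of cumulative adaptive culture, bounded by the number of
#' resource types.
#'
#' @param state a `sim_state`.
#' @return Mean traits per individual, or `NA` for an empty population.
#' @export
mean_traits <- function(state) {
  if (nrow(state$individuals) == 0L) {
    return(NA_real_)
  }
  mean(rowSums(state$skills > 0L))
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Computes the Mann-Whitney statistic from midranks and an exact two-sided
#' p value under the permutation distribution of the rank sum (all
#' `choose(n_a + n_b, n_a)` labelings equally likely), via a subset-sum
#' recursion over doubled midranks.  Ties are handled by midranks with the
#' permutation-exact p; two identical samples give p = 1.
#'
#' @param sample_a,sample_b numeric end-value samples (nonempty).
#' @return One-row tibble with the Mann-Whitney `statistic` (U for
#'   `sample_a`), exact `p_value`, and the sample sizes.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)) # p = 0.1
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b) {
  na <- length(sample_a)
  nb <- length(sample_b)
  stopifnot(na >= 1, nb >= 1)
  n <- na + nb
  r <- rank(c(sample_a, sample_b)) # midranks
  z <- as.integer(round(2 * r)) # doubled midranks are integers
  wobs <- sum(z[seq_len(na)])
  smax <- sum(z)
  # counts[m + 1, s + 1] = number of m-subsets of z with doubled-rank sum s
  counts <- matrix(0, nrow = na + 1L, ncol = smax + 1L)
  counts[1L, 1L] <- 1
  for (zi in z) {
    m_hi <- min(na, n) # upper bound on subset size so far; na suffices
    for (m in seq(from = min(na, m_hi), to = 1L)) {
      idx <- seq_len(smax + 1L - zi)
      counts[m + 1L, idx + zi] <- counts[m + 1L, idx + zi] + counts[m, idx]
    }
  }
  dist <- counts[na + 1L, ]
  total <- sum(dist)
  p_le <- sum(dist[seq_len(wobs + 1L)]) / total
  p_ge <- sum(dist[(wobs + 1L):(smax + 1L)]) / total
  p <- min(1, 2 * min(p_le, p_ge))
  u <- wobs / 2 - na * (na + 1) / 2
  tibble::tibble(
    statistic = u, p_value = p, n_a = na, n_b = nb, exact = TRUE
  )
}

#' Bonferroni correction
#'
#' @param p raw p value(s).
#' @param m number of pairwise tests in the family.
#' @return `min(1, m * p)`, vectorised over `p`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Summarise sweep end values per parameter cell
#'
#' Means and sample (n-1) standard deviations of the end-of-run mean traits
#' per individual, mean group size and competition, per parameter cell,
#' across replicates.
#'
#' @param end_values tibble of per-replicate end values carrying the cell
#'   parameter columns (as produced by [run_sweep()]).
#' @param by cell-defining columns.
#' @return One row per cell with `n` and `<metric>_mean` / `<metric>_sd`
#'   columns.
#' @export
summarize_sweep <- function(end_values,
                            by = c(
                              "selection_differential", "resource_level",
                              "interaction_radius", "innovation_cost",
                              "learning_cost"
                            )) {
  by <- intersect(by, names(end_values))
  end_values |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(
        dplyr::all_of(c("mean_traits", "mean_group_size", "competition")),
        list(mean = ~ mean(.x), sd = ~ stats::sd(.x))
      ),
      .groups = "drop"
    )
}

#' Wide cell-summary table (isolated vs interacting columns)
#'
#' Reshapes a sweep summary into the conventional layout: one row per
#' (selection differential, resource level), group size and trait columns
#' side by side for the isolated (radius 1) and interacting (radius 2)
#' regimes, formatted as `mean +/- sd`.
#'
#' @param summary output of [summarize_sweep()].
#' @return A wide tibble.
#' @export
table1_layout <- function(summary) {
  fmt <- function(m, s) sprintf("%.2f±%.3f", m, s)
  summary |>
    dplyr::mutate(
      regime = ifelse(.data$interaction_radius == 1L, "isolated", "interacting"),
      group_size = fmt(.data$mean_group_size_mean, .data$mean_group_size_sd),
      n_traits = fmt(.data$mean_traits_mean, .data$mean_traits_sd)
    ) |>
    dplyr::select(
      "selection_differential", "resource_level", "regime",
      "group_size", "n_traits"
    ) |>
    tidyr::pivot_wider(
      names_from = "regime",
      values_from = c("group_size", "n_traits"),
      names_glue = "{regime}_{.value}"
    ) |>
    dplyr::arrange(.data$selection_differential, .data$resource_level)
}

#' Pairwise end-value comparisons with Bonferroni correction
#'
#' Runs exact Wilcoxon rank-sum tests on replicate end values between
#' parameter cells, three families as in the model's standard analysis:
#' across selection differentials holding (resource level, regime) fixed
#' (correction factor = number of pairs, 6 for the full design), across
#' resource levels holding (selection differential, regime) fixed (factor 3),
#' and between interaction regimes holding (selection differential, resource
#' level) fixed (factor 1).
#'
#' @param end_values tibble of per-replicate end values with cell columns.
#' @param metrics end-value columns to compare.
#' @return A tibble with one row per (family, fixed cell, pair, metric):
#'   statistic, raw and corrected p, correction factor, significance flags.
#' @export
compare_sweep <- function(end_values,
                          metrics = c(
                            "mean_traits", "mean_group_size", "competition"
                          )) {
  pairwise <- function(df, vary, fixed, family) {
    levels <- sort(unique(df[[vary]]))
    if (length(levels) < 2L) {
      return(NULL)
    }
    pairs <- utils::combn(levels, 2L, simplify = FALSE)
    m <- length(pairs)
    cells <- dplyr::distinct(df, dplyr::across(dplyr::all_of(fixed)))
    purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
      cell <- cells[ci, , drop = FALSE]
      sub <- dplyr::semi_join(df, cell, by = fixed)
      purrr::map_dfr(pairs, function(pr) {
        a <- sub[sub[[vary]] == pr[[1L]], , drop = FALSE]
        b <- sub[sub[[vary]] == pr[[2L]], , drop = FALSE]
        if (nrow(a) == 0L || nrow(b) == 0L) {
          return(NULL)
        }
        purrr::map_dfr(metrics, function(met) {
          w <- wilcoxon_rank_sum(a[[met]], b[[met]])
          dplyr::bind_cols(
            tibble::tibble(
              family = family, metric = met,
              varied = vary,
              level_a = pr[[1L]], level_b = pr[[2L]]
            ),
            cell,
            tibble::tibble(
              statistic = w$statistic, p_raw = w$p_value,
              bonferroni_m = m,
              p_corrected = bonferroni(w$p_value, m),
              sig_05 = bonferroni(w$p_value, m) < 0.05,
              sig_01 = bonferroni(w$p_value, m) < 0.01
            )
          )
        })
      })
    })
  }
  dplyr::bind_rows(
    pairwise(
      end_values, "selection_differential",
      c("resource_level", "interaction_radius"), "selection_differential"
    ),
    pairwise(
      end_values, "resource_level",
      c("selection_differential", "interaction_radius"), "resource_level"
    ),
    pairwise(
      end_values, "interaction_radius",
      c("selection_differential", "resource_level"), "interaction_regime"
    )
  )
}
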