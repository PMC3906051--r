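# Canned experiment sweeps over resource level, selection differential,
# interaction regime and innovation/learning costs.

#' Parameter cells of a named sweep
#'
#' The standard designs: `"table1"` crosses selection differentials
#' \{0.01, 0.1, 0.5, 1.0\} with resource levels \{50, 100, 500\} and both
#' interaction regimes at innovation cost 10 and no learning cost (24 cells);
#' `"fig1_learningcost"` is the same design with a learning cost of 1 energy
#' unit per learning event; `"fig2_innovationcost"` additionally crosses
#' innovation costs \{10, 20, 40\} (72 cells).
#'
#' @param name sweep name.
#' @param resource_levels optional subset of resource levels (desk-scale
#'   filtering).
#' @param radii optional subset of interaction radii.
#' @return A tibble of parameter cells with a stable `cell_index`.
#' @export
sweep_cells <- function(name = c("table1", "fig1_learningcost", "fig2_innovationcost"),
                        resource_levels = NULL, radii = NULL) {
  name <- match.arg(name)
  base <- tidyr::expand_grid(
    selection_differential = c(0.01, 0.1, 0.5, 1.0),
    resource_level = c(50, 100, 500),
    interaction_radius = c(1L, 2L)
  )
  cells <- switch(name,
    table1 = dplyr::mutate(base, innovation_cost = 10, learning_cost = 0),
    fig1_learningcost = dplyr::mutate(base, innovation_cost = 10, learning_cost = 1),
    fig2_innovationcost = tidyr::expand_grid(
      base,
      innovation_cost = c(10, 20, 40)
    ) |> dplyr::mutate(learning_cost = 0)
  )
  cells <- dplyr::mutate(cells, cell_index = dplyr::row_number(), .before = 1L)
  if (!is.null(resource_levels)) {
    cells <- dplyr::filter(cells, .data$resource_level %in% resource_levels)
  }
  if (!is.null(radii)) {
    cells <- dplyr::filter(cells, .data$interaction_radius %in% radii)
  }
  cells
}

#' Replicate seed for a sweep cell
#'
#' Seeds are `base_seed + (cell_index - 1) * n_runs + (replicate - 1)`, so
#' any cell can be re-run independently and reproducibly.
#' @noRd
.cell_seed <- function(base_seed, cell_index, n_runs, replicate) {
  as.integer(base_seed + (cell_index - 1L) * n_runs + (replicate - 1L))
}

#' Run an experiment sweep
#'
#' Runs `n_runs` replicate simulations per parameter cell and collects the
#' per-replicate end values, the per-cell summary and the pairwise
#' Bonferroni-corrected comparisons.
#'
#' @param cells a sweep name (see [sweep_cells()]) or a tibble of cells.
#' @param base_seed base RNG seed; replicate seeds are derived per cell so
#'   sweep output is a pure function of `(cells, base_seed, overrides)`.
#' @param n_runs replicates per cell.
#' @param n_steps run length; `NULL` uses the config default.
#' @param resource_levels,radii optional cell filters (passed to
#'   [sweep_cells()] when `cells` is a name).
#' @param config_overrides named list of additional [sim_config()] overrides
#'   applied to every cell.
#' @param outdir optional directory; when given, `end_values.csv`,
#'   `summary.csv` and `comparisons.csv` are written there.
#' @param keep_runs keep the full `sim_run` objects (memory-hungry for large
#'   sweeps).
#' @param quiet suppress per-cell progress messages.
#' @return A `sim_sweep` object: `cells`, `end_values`, `summary`,
#'   `comparisons` (and `runs` when `keep_runs = TRUE`).
#' @export
run_sweep <- function(cells, base_seed = 1L, n_runs = 10L, n_steps = NULL,
                      resource_levels = NULL, radii = NULL,
                      config_overrides = list(), outdir = NULL,
                      keep_runs = FALSE, quiet = TRUE) {
  if (is.character(cells)) {
    cells <- sweep_cells(cells, resource_levels = resource_levels, radii = radii)
  }
  stopifnot(nrow(cells) >= 1L, "cell_index" %in% names(cells))
  par_cols <- setdiff(names(cells), "cell_index")
  all_runs <- list()
  end_values <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, , drop = FALSE]
    over <- c(as.list(cell[par_cols]), config_overrides)
    if (!is.null(n_steps)) over$n_steps <- n_steps
    cfg <- sim_config(over)
    if (!quiet) {
      message(
        "cell ", cell$cell_index, "/", max(cells$cell_index), ": ",
        paste(par_cols, unlist(cell[par_cols]), sep = "=", collapse = " ")
      )
    }
    purrr::map_dfr(seq_len(n_runs), function(j) {
      seed <- .cell_seed(base_seed, cell$cell_index, n_runs, j)
      run <- run_sim(cfg, seed)
      if (keep_runs) all_runs[[length(all_runs) + 1L]] <<- run
      dplyr::bind_cols(cell, tibble::tibble(replicate = j), glance(run))
    })
  })
  out <- list(
    cells = cells,
    base_seed = as.integer(base_seed),
    n_runs = as.integer(n_runs),
    end_values = end_values,
    summary = summarize_sweep(end_values),
    comparisons = compare_sweep(end_values)
  )
  if (keep_runs) out$runs <- all_runs
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(end_values, file.path(outdir, "end_values.csv"))
    readr::write_csv(out$summary, file.path(outdir, "summary.csv"))
    readr::write_csv(out$comparisons, file.path(outdir, "comparisons.csv"))
  }
  structure(out, class = c("sim_sweep", "list"))
}

#' @export
print.sim_sweep <- function(x, ...) {
  cat(
    "<sim_sweep>", nrow(x$cells), "cells x", x$n_runs,
    "replicates (base seed", x$base_seed, ")\n"
  )
  print(x$summary)
  invisible(x)
}

#' @rdname run_sweep
#' @param x a `sim_sweep`.
#' @param ... unused.
#' @export
tidy.sim_sweep <- function(x, ...) x$end_values

#' @rdname run_sweep
#' @export
glance.sim_sweep <- function(x, ...) x$summary

#' Cell-summary bar plot for a sweep
#'
#' Mean end-of-run traits per individual (or another summarised metric) by
#' selection differential, coloured by resource level and faceted by
#' interaction regime, with +/- 1 SD error bars.
#'
#' @param object a `sim_sweep`.
#' @param metric one of `"mean_traits"`, `"mean_group_size"`,
#'   `"competition"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sim_sweep <- function(object, metric = "mean_traits", ...) {
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  dat <- object$summary |>
    dplyr::mutate(
      regime = ifelse(.data$interaction_radius == 1L, "isolated", "interacting"),
      sd_label = factor(.data$selection_differential),
      level = factor(.data$resource_level)
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$sd_label, y = .data[[mcol]], fill = .data$level
    )
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data[[mcol]] - .data[[scol]],
        ymax = .data[[mcol]] + .data[[scol]]
      ),
      position = ggplot2::position_dodge(0.9), width = 0.25
    ) +
    ggplot2::facet_wrap(~regime) +
    ggplot2::labs(
      x = "selection differential", y = metric,
      fill = "resource level"
    ) +
    ggplot2::theme_minimal()
}
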