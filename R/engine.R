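# Per-step scheduler driver and full-run / multi-run entry points.

.ts_cols <- c(
  "step", "population", "mean_group_size", "mean_traits", "competition",
  "n_groups"
)

#' Observables of a simulation state
#'
#' @param state a `sim_state`.
#' @return One-row tibble with `step`, `population`, `mean_group_size`,
#'   `mean_traits`, `competition` and `n_groups` (means are `NA` for an empty
#'   population).
#' @export
state_observables <- function(state) {
  pop <- nrow(state$individuals)
  ngr <- nrow(state$groups)
  tibble::tibble(
    step = as.integer(state$step),
    population = pop,
    mean_group_size = if (ngr > 0L) pop / ngr else NA_real_,
    mean_traits = if (pop > 0L) mean(rowSums(state$skills > 0L)) else NA_real_,
    competition = if (pop > 0L) mean(state$individuals$under_pressure) else NA_real_,
    n_groups = ngr
  )
}

#' Advance a simulation state
#'
#' Runs `n_steps` steps of the per-step schedule: (1) replenish resources,
#' (2) shuffle the individual processing order, (3) per individual metabolize,
#' forage and check death, (4) per survivor in the same order learn/invent if
#' under pressure then search for a partner and reproduce if eligible,
#' (5) per group fission or migrate under pressure, (6) record observables.
#' Newborns do not act until the following step.  The run stops early if the
#' population goes extinct.
#'
#' @param state a `sim_state`.
#' @param n_steps number of steps to advance.
#' @return The updated `sim_state`; the per-step observables and innovation
#'   events accumulate in `state$timeseries` and `state$events`.
#' @export
sim_step <- function(state, n_steps = 1L) {
  stopifnot(inherits(state, "sim_state"), n_steps >= 0)
  if (n_steps == 0L) {
    return(state)
  }
  res <- cpp_run(state, state$config, as.integer(n_steps))
  new <- res$state
  ts <- res$timeseries
  colnames(ts) <- .ts_cols
  ts <- tibble::as_tibble(ts) |>
    dplyr::mutate(
      step = as.integer(.data$step),
      population = as.integer(.data$population),
      n_groups = as.integer(.data$n_groups)
    )
  ev <- res$events
  events <- tibble::tibble(
    step = as.integer(ev[, 1]),
    group_id = as.integer(ev[, 2]),
    trait_index = as.integer(ev[, 3]),
    individual_id = ev[, 4]
  )
  out <- state
  out$step <- new$step
  out$stocks <- new$stocks
  out$square_group <- new$square_group
  out$groups <- tibble::as_tibble(new$groups)
  out$individuals <- tibble::as_tibble(new$individuals)
  out$skills <- new$skills
  out$next_ind_id <- new$next_ind_id
  out$next_group_id <- new$next_group_id
  out$events <- dplyr::bind_rows(state$events, events)
  out$timeseries <- dplyr::bind_rows(state$timeseries, ts)
  out$extinct <- isTRUE(res$extinct)
  out
}

#' Execute a full simulation run
#'
#' Initialises the world from `(config, seed)` and advances it `n_steps`
#' steps, returning the per-step time series (population, mean group size,
#' mean traits per individual, competition, group count), the innovation
#' event log, the end values at the final step, and the final state.  A run
#' whose population goes extinct stops early and is flagged; its end values
#' are taken at the last step with a living population.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed (defaults to `config$seed`).
#' @param n_steps run length in steps (defaults to `config$n_steps`).
#' @return A `sim_run` object.
#' @examples
#' run <- run_sim(sim_config(n_steps = 25), seed = 1)
#' glance(run)
#' @export
run_sim <- function(config, seed = config$seed, n_steps = config$n_steps) {
  if (is.null(seed) || is.na(seed)) {
    stop("run_sim needs a seed (argument or config$seed)", call. = FALSE)
  }
  state <- init_world(config, seed)
  state$timeseries <- state_observables(state)
  state <- sim_step(state, n_steps)
  ts <- state$timeseries
  alivets <- dplyr::filter(ts, .data$population > 0L)
  end_values <- if (nrow(alivets)) {
    dplyr::slice_tail(alivets, n = 1L)
  } else {
    dplyr::slice_tail(ts, n = 1L)
  }
  structure(
    list(
      config = state$config,
      seed = as.integer(seed),
      n_steps = as.integer(n_steps),
      timeseries = ts,
      events = state$events,
      end_values = end_values,
      extinct = isTRUE(state$extinct),
      final_state = state
    ),
    class = c("sim_run", "list")
  )
}

#' Run independent replicate simulations
#'
#' Replicate `i` uses seed `base_seed + i - 1`; results are returned in seed
#' order.
#'
#' @param config a [sim_config()].
#' @param base_seed seed of the first replicate.
#' @param n_runs number of replicates (defaults to `config$n_runs`).
#' @param n_steps run length (defaults to `config$n_steps`).
#' @return A `sim_experiment` object: the list of `sim_run`s plus an
#'   end-value table, one row per replicate.
#' @export
run_replicates <- function(config, base_seed, n_runs = config$n_runs,
                           n_steps = config$n_steps) {
  stopifnot(n_runs >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  runs <- purrr::map(seeds, function(s) run_sim(config, s, n_steps))
  structure(
    list(
      config = config,
      base_seed = as.integer(base_seed),
      runs = runs,
      end_values = purrr::map_dfr(runs, glance)
    ),
    class = c("sim_experiment", "list")
  )
}

#' @export
print.sim_run <- function(x, ...) {
  ev <- x$end_values
  cat(
    "<sim_run> seed", x$seed, "|", max(x$timeseries$step), "steps",
    if (x$extinct) "(extinct)" else "", "\n",
    " end values: population", ev$population,
    "| mean traits", signif(ev$mean_traits, 4),
    "| mean group size", signif(ev$mean_group_size, 4),
    "| competition", signif(ev$competition, 4), "\n"
  )
  invisible(x)
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("<sim_experiment>", length(x$runs), "replicates, base seed", x$base_seed, "\n")
  print(x$end_values)
  invisible(x)
}

#' @rdname run_sim
#' @param x a `sim_run` or `sim_experiment`.
#' @param ... unused.
#' @export
tidy.sim_run <- function(x, ...) x$timeseries

#' @rdname run_sim
#' @export
glance.sim_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(seed = x$seed, extinct = x$extinct),
    x$end_values
  )
}

#' @rdname run_replicates
#' @param x a `sim_experiment`.
#' @param ... unused.
#' @export
tidy.sim_experiment <- function(x, ...) {
  purrr::imap_dfr(x$runs, function(r, i) {
    dplyr::mutate(r$timeseries, run = i, seed = r$seed, .before = 1L)
  })
}

#' @rdname run_replicates
#' @export
glance.sim_experiment <- function(x, ...) x$end_values

#' Population trajectory plot for a run
#'
#' Plots the population time series with the innovation events marked;
#' growth-phase onsets follow the invention and spread of new traits, giving
#' the characteristic staircase of sequential logistic growth phases.
#'
#' @param object a `sim_run`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sim_run <- function(object, ...) {
  firsts <- if (nrow(object$events)) {
    object$events |>
      dplyr::group_by(.data$trait_index) |>
      dplyr::summarise(step = min(.data$step), .groups = "drop")
  } else {
    object$events
  }
  p <- ggplot2::ggplot(
    object$timeseries,
    ggplot2::aes(x = .data$step, y = .data$population)
  ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "step (years)", y = "population",
      title = "Population trajectory",
      subtitle = "dashed lines: first invention of each trait"
    ) +
    ggplot2::theme_minimal()
  if (nrow(firsts)) {
    p <- p + ggplot2::geom_vline(
      data = firsts, ggplot2::aes(xintercept = .data$step),
      linetype = "dashed", colour = "grey50"
    )
  }
  p
}

#' Mean trajectory across replicates
#'
#' Mean per-step population (or another observable) across the replicates of
#' an experiment, the form in which growth plateaus and innovation-driven
#' growth phases are usually inspected.
#'
#' @param object a `sim_experiment`.
#' @param metric observable column to average.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sim_experiment <- function(object, metric = "population", ...) {
  dat <- tidy(object) |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "step (years)", y = paste("mean", metric),
      title = paste("Replicate-mean", metric, "trajectory")
    ) +
    ggplot2::theme_minimal()
}

#' Write the artifacts of a run to a directory
#'
#' Writes `timeseries.csv`, `events.csv` (step, group_id, trait_index),
#' `end_values.json` and the fully resolved `config.resolved.json`.
#'
#' @param run a `sim_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$timeseries, file.path(dir, "timeseries.csv"))
  readr::write_csv(
    dplyr::select(run$events, "step", "group_id", "trait_index"),
    file.path(dir, "events.csv")
  )
  jsonlite::write_json(
    c(list(seed = run$seed, extinct = run$extinct), as.list(run$end_values)),
    file.path(dir, "end_values.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  save_config(run$config, file.path(dir, "config.resolved.json"))
  invisible(dir)
}
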