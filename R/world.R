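# Grid creation, resource replenishment, neighbourhood geometry, and the
# sim_state container shuttled between R and the compiled engine.

#' Map 0-based square coordinates to a row index of the stocks matrix
#' @noRd
.square_index <- function(col, row, width) row * width + col + 1L

#' Initialise the simulation world
#'
#' Builds the grid with every resource stock at `resource_level` and places a
#' founding group of 20 individuals (balanced sexes, ages uniform on 15-30,
#' energy 25, holding only trait 1 at skill 1) on a uniformly random square.
#' Seeding the RNG here makes the whole run reproducible from
#' `(config, seed)`.
#'
#' @param config a [sim_config()] object.
#' @param seed integer RNG seed; `NULL` keeps the current RNG state.
#' @return A `sim_state` object: grid stocks, groups, individuals, skill
#'   matrix, step counter and innovation-event log.
#' @export
init_world <- function(config, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  nsq <- config$grid_width * config$grid_height
  nt <- config$n_resource_types
  stocks <- matrix(config$resource_level, nrow = nsq, ncol = nt)
  sq <- sample.int(nsq, 1L) - 1L # 0-based
  col <- sq %% config$grid_width
  row <- sq %/% config$grid_width
  n0 <- 20L
  individuals <- tibble::tibble(
    id = as.numeric(seq_len(n0)),
    sex = rep(c(0L, 1L), each = n0 %/% 2L),
    age = sample(15:30, n0, replace = TRUE),
    energy = rep(25, n0),
    group_id = rep(1L, n0),
    intake = rep(0, n0),
    under_pressure = rep(FALSE, n0)
  )
  skills <- matrix(0L, nrow = n0, ncol = nt)
  skills[, 1L] <- 1L
  square_group <- rep(NA_integer_, nsq)
  square_group[sq + 1L] <- 1L
  state <- list(
    config = config,
    step = 0L,
    stocks = stocks,
    square_group = square_group,
    groups = tibble::tibble(id = 1L, col = col, row = row),
    individuals = individuals,
    skills = skills,
    events = .empty_events(),
    next_ind_id = n0 + 1,
    next_group_id = 2L
  )
  structure(state, class = c("sim_state", "list"))
}

.empty_events <- function() {
  tibble::tibble(
    step = integer(), group_id = integer(), trait_index = integer(),
    individual_id = numeric()
  )
}

#' Reset all resource stocks to the configured level
#'
#' Resources are a per-step flow: every stock of every square returns to
#' `resource_level` at the start of a step, so depletion only acts within a
#' time step.
#'
#' @param state a `sim_state`.
#' @return The state with a fully replenished grid.
#' @export
replenish_resources <- function(state) {
  state$stocks[] <- state$config$resource_level
  state
}

#' Moore neighbourhood of a grid square
#'
#' Returns the up-to-eight squares surrounding `(col, row)` on a bounded grid
#' (0-based coordinates, no wraparound: edges and corners have fewer
#' neighbours).
#'
#' @param col,row 0-based square coordinates.
#' @param grid_width,grid_height grid dimensions in squares.
#' @return A tibble with columns `col` and `row`, one row per neighbour.
#' @examples
#' moore_neighbours(0, 0, 10, 10) # corner: 3 neighbours
#' @export
moore_neighbours <- function(col, row, grid_width = 10L, grid_height = 10L) {
  stopifnot(length(col) == 1L, length(row) == 1L)
  if (col < 0 || col >= grid_width || row < 0 || row >= grid_height) {
    stop("coordinates (", col, ",", row, ") are off the grid", call. = FALSE)
  }
  out <- tidyr::expand_grid(dc = -1:1, dr = -1:1) |>
    dplyr::filter(.data$dc != 0L | .data$dr != 0L) |>
    dplyr::transmute(col = col + .data$dc, row = row + .data$dr) |>
    dplyr::filter(
      .data$col >= 0L, .data$col < grid_width,
      .data$row >= 0L, .data$row < grid_height
    )
  out
}

#' @export
print.sim_state <- function(x, ...) {
  cat(
    "<sim_state> step", x$step, "|", nrow(x$individuals), "individuals in",
    nrow(x$groups), "group(s) on a", x$config$grid_width, "x",
    x$config$grid_height, "grid\n"
  )
  invisible(x)
}

#' Individuals of a simulation state as a tibble
#'
#' @param x a `sim_state`.
#' @param ... unused.
#' @return The individual table with the trait count `n_traits` and a
#'   `skills` list-column appended.
#' @export
as_tibble.sim_state <- function(x, ...) {
  k <- rowSums(x$skills > 0L)
  dplyr::mutate(
    x$individuals,
    n_traits = as.integer(k),
    skills = purrr::map(seq_len(nrow(x$skills)), function(i) {
      v <- x$skills[i, ]
      v[v > 0L]
    })
  )
}
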