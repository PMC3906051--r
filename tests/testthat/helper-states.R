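# Builders for small hand-made simulation states used across the tests.

# A sim_state with explicitly placed groups and individuals.
# groups: tibble(id, col, row); individuals: tibble(id, sex, age, energy,
# group_id); skills: integer matrix (rows match individuals).
make_test_state <- function(config, groups, individuals, skills) {
  nsq <- config$grid_width * config$grid_height
  stocks <- matrix(config$resource_level,
    nrow = nsq,
    ncol = config$n_resource_types
  )
  square_group <- rep(NA_integer_, nsq)
  if (nrow(groups)) {
    idx <- groups$row * config$grid_width + groups$col + 1L
    square_group[idx] <- groups$id
  }
  if (!"intake" %in% names(individuals)) individuals$intake <- 0
  if (!"under_pressure" %in% names(individuals)) {
    individuals$under_pressure <- FALSE
  }
  individuals$id <- as.numeric(individuals$id)
  skills <- matrix(as.integer(skills),
    nrow = nrow(individuals),
    ncol = config$n_resource_types
  )
  structure(
    list(
      config = config,
      step = 0L,
      stocks = stocks,
      square_group = square_group,
      groups = groups,
      individuals = individuals,
      skills = skills,
      events = culturesim:::.empty_events(),
      next_ind_id = if (nrow(individuals)) max(individuals$id) + 1 else 1,
      next_group_id = if (nrow(groups)) max(groups$id) + 1L else 1L
    ),
    class = c("sim_state", "list")
  )
}

# Skills matrix row from a trait-value vector, zero-padded to n types.
skill_row <- function(values, n_types = 10L) {
  out <- rep(0L, n_types)
  out[seq_along(values)] <- as.integer(values)
  out
}

# n individuals in one group with identical fields.
flat_inds <- function(n, group_id = 1L, sex = rep(c(0L, 1L), length.out = n),
                      age = 20L, energy = 40) {
  tibble::tibble(
    id = seq_len(n), sex = sex, age = rep(age, length.out = n),
    energy = rep(energy, length.out = n), group_id = group_id
  )
}

# Assert the structural invariants of a state: energy and stock bounds, the
# prefix trait rule, skill bounds, unique ids, group <-> square consistency.
expect_state_invariants <- function(state) {
  cfg <- state$config
  expect_true(all(state$individuals$energy >= 0))
  expect_true(all(state$individuals$energy <= cfg$energy_cap + 1e-9))
  expect_true(all(state$stocks >= -1e-9))
  expect_true(all(state$stocks <= cfg$resource_level + 1e-9))
  expect_false(any(duplicated(state$individuals$id)))
  expect_false(any(duplicated(state$groups$id)))
  # prefix rule: positive skills occupy columns 1..k with values in range
  k <- rowSums(state$skills > 0L)
  for (i in seq_len(nrow(state$skills))) {
    expect_identical(which(state$skills[i, ] > 0L), seq_len(k[i]))
  }
  expect_true(all(state$skills <= cfg$max_skill))
  expect_true(all(k >= 1L) || nrow(state$individuals) == 0L)
  # every member's group exists; groups occupy distinct squares
  expect_true(all(state$individuals$group_id %in% state$groups$id))
  sq <- state$groups$row * cfg$grid_width + state$groups$col + 1L
  expect_false(any(duplicated(sq)))
  expect_identical(
    sort(state$square_group[!is.na(state$square_group)]),
    sort(state$groups$id)
  )
}
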