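# Partner search, reproduction with energy transfer, and group-level
# pressure metrics.  Fission/migration itself runs inside the engine; the
# group-pressure metric it is driven by is exposed here.

#' Find a reproduction partner
#'
#' A uniformly random eligible partner for `individual_id`: opposite sex, at
#' least the minimum reproductive age, energy at or above the reproduction
#' threshold, and not in `exclude` (ids already paired this step).  The search
#' covers the individual's own group, extended to groups on
#' Moore-neighbouring squares when the interaction radius is 2.
#'
#' @param state a `sim_state`.
#' @param individual_id id of the searching individual.
#' @param exclude numeric vector of ids unavailable this step.
#' @return The partner's id, or `NA` if no candidate exists.
#' @export
find_partner <- function(state, individual_id, exclude = numeric()) {
  cfg <- state$config
  inds <- state$individuals
  me <- dplyr::filter(inds, .data$id == individual_id)
  if (nrow(me) != 1L) stop("unknown individual id", call. = FALSE)
  if (me$age < cfg$min_repro_age || me$energy < cfg$repro_energy_threshold) {
    return(NA_real_)
  }
  gids <- .reachable_groups(state, me$group_id)
  cand <- dplyr::filter(
    inds,
    .data$group_id %in% gids,
    .data$sex != me$sex,
    .data$age >= cfg$min_repro_age,
    .data$energy >= cfg$repro_energy_threshold,
    !(.data$id %in% c(individual_id, exclude))
  )
  if (nrow(cand) == 0L) {
    return(NA_real_)
  }
  cand$id[sample.int(nrow(cand), 1L)]
}

#' Create a newborn from a parent pair
#'
#' The newborn starts at age 0 with energy `2 * birth_energy_transfer`
#' (each parent transfers `birth_energy_transfer` units), joins the mother's
#' group, and receives its trait list by [vertical_transmission()].
#'
#' @param state a `sim_state`.
#' @param mother_id,father_id parent ids (female and male respectively).
#' @return The updated state; the newborn is the last row of
#'   `state$individuals`.
#' @export
reproduce <- function(state, mother_id, father_id) {
  cfg <- state$config
  inds <- state$individuals
  mi <- which(inds$id == mother_id)
  fi <- which(inds$id == father_id)
  stopifnot(length(mi) == 1L, length(fi) == 1L)
  if (inds$sex[mi] != 0L || inds$sex[fi] != 1L) {
    stop("mother must be female (sex 0) and father male (sex 1)", call. = FALSE)
  }
  msk <- state$skills[mi, ]
  fsk <- state$skills[fi, ]
  child_sk <- vertical_transmission(
    msk[msk > 0L], fsk[fsk > 0L], cfg$copy_error_prob, cfg$max_skill
  )
  inds$energy[c(mi, fi)] <-
    pmax(0, inds$energy[c(mi, fi)] - cfg$birth_energy_transfer)
  newborn <- tibble::tibble(
    id = as.numeric(state$next_ind_id),
    sex = sample(0:1, 1L),
    age = 0L,
    energy = 2 * cfg$birth_energy_transfer,
    group_id = inds$group_id[mi],
    intake = 0,
    under_pressure = FALSE
  )
  state$individuals <- dplyr::bind_rows(inds, newborn)
  srow <- rep(0L, cfg$n_resource_types)
  srow[seq_along(child_sk)] <- child_sk
  state$skills <- rbind(state$skills, srow)
  state$next_ind_id <- state$next_ind_id + 1
  state
}

#' Per-group resource pressure
#'
#' The fraction of each group's members that could not meet the minimum
#' per-step intake this step; this is the quantity that triggers fission or
#' migration when it exceeds `pressure_fission_fraction`.
#'
#' @param state a `sim_state`.
#' @return A tibble with `group_id`, group `size` and `fraction_unmet`.
#' @export
group_pressure <- function(state) {
  state$individuals |>
    dplyr::group_by(group_id = .data$group_id) |>
    dplyr::summarise(
      size = dplyr::n(),
      fraction_unmet = mean(.data$under_pressure),
      .groups = "drop"
    )
}
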