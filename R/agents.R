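# Individual energy budget: extraction, metabolism, foraging, mortality.

#' Skill-dependent resource extraction rate
#'
#' The amount of a resource an individual can extract per step with one trait:
#' `basic_rate + selection_differential * (skill - 1)`.  The basic rate is the
#' consumption rate at skill 1; the selection differential is the increase in
#' extraction rate per one-unit increase in skill and sets the intensity of
#' selection on skill.
#'
#' @param basic_rate extraction rate at skill 1 (resource units per step).
#' @param selection_differential extra units per skill step.
#' @param skill integer skill value(s), each `>= 1`.
#' @return Extraction rate(s), vectorised over `skill`.
#' @examples
#' extraction_rate(5, 0.5, 1) # 5
#' extraction_rate(5, 1, 4) # 8
#' @export
extraction_rate <- function(basic_rate, selection_differential, skill) {
  if (any(skill < 1)) stop("skill must be >= 1", call. = FALSE)
  basic_rate + selection_differential * (skill - 1)
}

#' Per-step metabolic expenditure and ageing
#'
#' Deducts the step requirement from the energy store (floored at zero, with
#' a starvation mark when the deduction could not be met in full) and ages
#' the individual by one year.
#'
#' @param individual a list or one-row tibble with fields `age` and `energy`.
#' @param config a [sim_config()].
#' @return The individual with updated `age`, `energy` and a logical
#'   `starving` field.
#' @export
metabolize <- function(individual, config) {
  individual$starving <- individual$energy < config$step_requirement
  individual$energy <- max(0, individual$energy - config$step_requirement)
  individual$age <- individual$age + 1L
  individual
}

#' Greedy foraging on the local square
#'
#' Traits are exploited in descending order of current extraction rate (ties
#' broken by trait index); each contributes at most its rate, the remaining
#' stock of its resource, and the remaining storage headroom
#' (`energy_cap - energy`).  Under the default `forage_mode = "to_cap"` the
#' individual fills its store; under `"to_requirement"` it stops once the
#' per-step requirement is met.  The individual is under resource pressure
#' iff realised intake falls short of the step requirement.
#'
#' @param skills integer vector of owned trait skill values (prefix order).
#' @param energy current energy store.
#' @param stocks numeric vector of the square's per-resource stocks (at least
#'   as long as `skills`).
#' @param config a [sim_config()].
#' @return A list with `energy`, depleted `stocks`, `intake` and
#'   `under_pressure`.
#' @export
forage <- function(skills, energy, stocks, config) {
  cpp_forage(
    as.integer(skills), energy, as.numeric(stocks),
    config$basic_rate, config$selection_differential,
    config$energy_cap, config$step_requirement,
    identical(config$forage_mode, "to_requirement")
  )
}

#' Mortality rule
#'
#' An individual dies when its energy store is exhausted after foraging or
#' when it exceeds the maximum age.
#'
#' @param age age in years.
#' @param energy energy store after foraging.
#' @param config a [sim_config()].
#' @return `TRUE` if the individual stays alive.
#' @export
check_death <- function(age, energy, config) {
  energy > 0 & age <= config$max_age
}
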