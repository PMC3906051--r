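# Cultural transmission: copy error, vertical transmission, oblique social
# learning, and invention of new traits.

#' Copy a skill value with transmission error
#'
#' With probability `error_prob` the copied value shifts one unit up or down
#' (equal odds), clamped to `[1, max_skill]`; otherwise it is copied
#' faithfully.  This +/-1 copying error is the model's only source of skill
#' variation (modification innovation).
#'
#' @param values integer skill value(s) to copy.
#' @param error_prob copying error probability (model default 0.05).
#' @param max_skill skill cap.
#' @return Integer vector of copied values.
#' @export
copy_with_error <- function(values, error_prob = 0.05, max_skill = 10L) {
  stopifnot(error_prob >= 0, error_prob <= 1)
  if (any(values < 1 | values > max_skill)) {
    stop("values must lie in [1, max_skill]", call. = FALSE)
  }
  cpp_copy_with_error(as.integer(values), error_prob, as.integer(max_skill))
}

#' Vertical transmission of the trait list at birth
#'
#' The newborn receives `min(k_mother, k_father)` traits (keeping the trait
#' list a prefix); each value is copied from a uniformly chosen parent holding
#' that trait, through the copying error.
#'
#' @param mother_skills,father_skills integer skill vectors of the parents.
#' @param error_prob copying error probability.
#' @param max_skill skill cap.
#' @return Integer skill vector of the newborn.
#' @export
vertical_transmission <- function(mother_skills, father_skills,
                                  error_prob = 0.05, max_skill = 10L) {
  stopifnot(length(mother_skills) >= 1, length(father_skills) >= 1)
  cpp_vertical_transmission(
    as.integer(mother_skills), as.integer(father_skills),
    error_prob, as.integer(max_skill)
  )
}

#' Candidate cultural models for a learner
#'
#' All living individuals in the learner's group other than the learner,
#' extended to the members of groups on Moore-neighbouring squares when the
#' interaction radius is 2.
#'
#' @param state a `sim_state`.
#' @param learner_id id of the learning individual.
#' @return A tibble of candidate individuals (columns as in
#'   [as_tibble.sim_state()]).
#' @export
find_cultural_models <- function(state, learner_id) {
  inds <- as_tibble(state)
  me <- dplyr::filter(inds, .data$id == learner_id)
  if (nrow(me) != 1L) stop("unknown learner id", call. = FALSE)
  gids <- .reachable_groups(state, me$group_id)
  dplyr::filter(inds, .data$group_id %in% gids, .data$id != learner_id)
}

# Group ids reachable for learning / partner search from group `gid`.
.reachable_groups <- function(state, gid) {
  if (state$config$interaction_radius == 1L) {
    return(gid)
  }
  g <- dplyr::filter(state$groups, .data$id == gid)
  nb <- moore_neighbours(
    g$col, g$row, state$config$grid_width, state$config$grid_height
  )
  nb_ids <- state$square_group[.square_index(nb$col, nb$row, state$config$grid_width)]
  c(gid, nb_ids[!is.na(nb_ids)])
}

#' One social-learning attempt
#'
#' Applies the learning preference order: (a) acquire trait `k+1` from a
#' uniformly chosen model already holding it, else (b) improve a uniformly
#' chosen owned trait for which some model is strictly better, copying the
#' value of a uniformly chosen model holding that trait (so variants spread
#' in proportion to their carrier frequency and skill escalation is driven
#' by selection on carriers, not by the learning rule).  Either route passes
#' the copied value through the copying error and, on success, deducts the
#' learning cost from the
#' learner's energy (not below zero).  Learning fails when no eligible model
#' exists or the learner's energy does not exceed the learning cost.
#'
#' @param learner_skills integer skill vector of the learner.
#' @param learner_energy energy store of the learner.
#' @param model_skills integer matrix of candidate models' skills, one row per
#'   model, `n_resource_types` columns, zero marking an absent trait.
#' @param config a [sim_config()].
#' @return A list with updated `skills`, `energy` and logical `learned`.
#' @export
social_learning_event <- function(learner_skills, learner_energy,
                                  model_skills, config) {
  if (!is.matrix(model_skills)) {
    model_skills <- if (length(model_skills)) {
      matrix(as.integer(model_skills), nrow = 1L)
    } else {
      matrix(integer(), nrow = 0L, ncol = config$n_resource_types)
    }
  }
  storage.mode(model_skills) <- "integer"
  cpp_social_learn(
    as.integer(learner_skills), learner_energy,
    model_skills, config$copy_error_prob, config$max_skill,
    config$learning_cost, config$n_resource_types
  )
}

#' Attempt to invent a new trait
#'
#' Invention is gated on experience: it succeeds iff the individual's last
#' owned trait is at the maximum skill level, the trait list is not yet full,
#' and energy strictly exceeds the innovation cost.  On success the next
#' trait is added at skill 1 and the cost is deducted.
#'
#' @param skills integer skill vector of the inventor.
#' @param energy energy store.
#' @param config a [sim_config()].
#' @return A list with updated `skills`, `energy` and logical `invented`.
#' @export
attempt_invention <- function(skills, energy, config) {
  k <- length(skills)
  ok <- k >= 1L && k < config$n_resource_types &&
    skills[k] == config$max_skill && energy > config$innovation_cost
  if (!ok) {
    return(list(skills = as.integer(skills), energy = energy, invented = FALSE))
  }
  list(
    skills = c(as.integer(skills), 1L),
    energy = energy - config$innovation_cost,
    invented = TRUE
  )
}
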