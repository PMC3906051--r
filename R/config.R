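# Single source of truth for model parameters and their defaults.

.cs_defaults <- function() {
  list(
    grid_width = 10L,
    grid_height = 10L,
    n_resource_types = 10L,
    resource_level = 50,
    selection_differential = 0.1,
    basic_rate = 6,
    max_skill = 10L,
    copy_error_prob = 0.05,
    innovation_cost = 10,
    learning_cost = 0,
    interaction_radius = 1L,
    energy_cap = 50,
    step_requirement = 5,
    min_repro_age = 15L,
    repro_energy_threshold = 20,
    birth_energy_transfer = 10,
    max_age = 60L,
    fission_min_size = 10L,
    pressure_fission_fraction = 0.3,
    forage_mode = "to_requirement",
    replenish_mode = "reset",
    n_steps = 1000L,
    n_runs = 10L,
    seed = NA_integer_
  )
}

#' Create a validated simulation configuration
#'
#' Builds the full parameter set of the model, filling every field not
#' supplied with its documented default.  The parameters are, in units of the
#' model: grid dimensions (squares), number of resource types (equals the
#' maximum trait-list length), resource units delivered per type per square
#' per step (`resource_level`), the selection differential (extra extraction
#' units per skill step), the basic extraction rate at skill 1, the skill cap
#' per trait, the copying error probability, energetic costs of invention and
#' of a learning event, the interaction radius (1 = within-group only, 2 =
#' Moore neighbourhood, applied jointly to learning and partner search), the
#' individual energy cap and per-step metabolic requirement, reproduction
#' constraints (minimum age, minimum energy, energy transferred per parent to
#' the newborn), the maximum age, group fission thresholds, the foraging mode,
#' and run-length bookkeeping (`n_steps`, `n_runs`, `seed`).
#'
#' @param ... named parameter overrides; unknown names are an error.
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(selection_differential = 0.5, resource_level = 100)
#' cfg$interaction_radius
#' @export
sim_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  defaults <- .cs_defaults()
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("all configuration overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
  }
  cfg <- utils::modifyList(defaults, over)
  int_fields <- c(
    "grid_width", "grid_height", "n_resource_types", "max_skill",
    "interaction_radius", "min_repro_age", "max_age", "fission_min_size",
    "n_steps", "n_runs"
  )
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$seed <- if (is.null(cfg$seed) || all(is.na(cfg$seed))) {
    NA_integer_
  } else {
    as.integer(cfg$seed)
  }
  validate_config(cfg)
  structure(cfg, class = c("sim_config", "list"))
}

#' Validate a simulation configuration
#'
#' Checks every model invariant on the parameter set and stops with a
#' descriptive message on the first violation.
#'
#' @param cfg a named list of parameters (all fields present).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$grid_width) && cfg$grid_width >= 1, "grid_width must be >= 1")
  chk(num1(cfg$grid_height) && cfg$grid_height >= 1, "grid_height must be >= 1")
  chk(
    num1(cfg$n_resource_types) && cfg$n_resource_types >= 1 &&
      cfg$n_resource_types <= 16,
    "n_resource_types must be in 1..16"
  )
  chk(
    num1(cfg$resource_level) && cfg$resource_level > cfg$step_requirement,
    "resource_level must exceed step_requirement (habitability)"
  )
  chk(
    num1(cfg$selection_differential) && cfg$selection_differential >= 0,
    "selection_differential must be >= 0"
  )
  chk(num1(cfg$basic_rate) && cfg$basic_rate > 0, "basic_rate must be > 0")
  chk(num1(cfg$max_skill) && cfg$max_skill >= 1, "max_skill must be >= 1")
  chk(
    num1(cfg$copy_error_prob) && cfg$copy_error_prob >= 0 &&
      cfg$copy_error_prob <= 1,
    "copy_error_prob must lie in [0, 1]"
  )
  for (f in c(
    "innovation_cost", "learning_cost", "energy_cap", "step_requirement",
    "repro_energy_threshold", "birth_energy_transfer"
  )) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0, paste(f, "must be >= 0"))
  }
  chk(
    num1(cfg$interaction_radius) && cfg$interaction_radius %in% c(1L, 2L),
    "interaction_radius must be 1 (within-group) or 2 (Moore neighbourhood)"
  )
  chk(num1(cfg$min_repro_age) && cfg$min_repro_age >= 0, "min_repro_age must be >= 0")
  chk(num1(cfg$max_age) && cfg$max_age >= 1, "max_age must be >= 1")
  chk(num1(cfg$fission_min_size) && cfg$fission_min_size >= 2, "fission_min_size must be >= 2")
  chk(
    num1(cfg$pressure_fission_fraction) && cfg$pressure_fission_fraction >= 0 &&
      cfg$pressure_fission_fraction <= 1,
    "pressure_fission_fraction must lie in [0, 1]"
  )
  chk(
    is.character(cfg$forage_mode) &&
      cfg$forage_mode %in% c("to_cap", "to_requirement"),
    "forage_mode must be 'to_cap' or 'to_requirement'"
  )
  chk(
    is.character(cfg$replenish_mode) && cfg$replenish_mode == "reset",
    "replenish_mode: only 'reset' is implemented"
  )
  chk(num1(cfg$n_steps) && cfg$n_steps >= 0, "n_steps must be >= 0")
  chk(num1(cfg$n_runs) && cfg$n_runs >= 1, "n_runs must be >= 1")
  invisible(cfg)
}

#' Load a simulation configuration from a YAML or JSON file
#'
#' The file may specify any subset of the documented keys; missing keys take
#' their defaults and unknown keys are rejected.  The format is chosen from
#' the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path path to the configuration file.
#' @return A validated [sim_config()] object with all defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yaml" = ,
    "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)", call. = FALSE)
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a mapping of keys", call. = FALSE)
  sim_config(raw)
}

#' Save a simulation configuration
#'
#' Writes the fully resolved parameter set (defaults included) so that
#' `load_config(save_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param cfg a [sim_config()] object.
#' @param path output path; format chosen from the extension as in
#'   [load_config()].
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "yaml" = ,
    "yml" = yaml::write_yaml(x, path),
    "json" = jsonlite::write_json(x, path,
      auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
    ),
    stop("unsupported config format: .", ext, " (use YAML or JSON)", call. = FALSE)
  )
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  vals <- vapply(unclass(x), function(v) paste(format(v), collapse = ","), "")
  cat(paste0("  ", format(names(vals)), " : ", vals, collapse = "\n"), "\n")
  invisible(x)
}
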