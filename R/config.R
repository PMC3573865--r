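#' Run configuration: every tunable default in one serialisable object
#'
#' Collects the mass constants, the pipetting-error model, the panel QC
#' thresholds, the detection threshold and the balancing knobs, so a whole
#' calibration run is reproducible from one JSON file.
#'
#' @param mass_constants a [mass_constants()] object.
#' @param error_model a [pipetting_error_model()].
#' @param tm_tolerance Tm spread tolerance, degrees C.
#' @param tm_method `"wallace"` or `"nearest_neighbor"`.
#' @param dimer_score_threshold,dimer_anchored_threshold dimer run-length
#'   thresholds.
#' @param platform separation platform.
#' @param degraded_max_len degraded-DNA amplicon limit, bp.
#' @param detection_threshold detection bound, RFU.
#' @param balance_tolerance,balance_step,balance_bounds balancing knobs (see
#'   [balance_state()]).
#' @param max_step_factor,step_volume dilution planner knobs (see
#'   [plan_serial_dilution()]).
#' @param seed integer seed for randomised fixtures.
#' @return object of class `plexcal_config` (a named list).
#' @export
plexcal_config <- function(mass_constants = plexcal::mass_constants(),
                           error_model = pipetting_error_model(),
                           tm_tolerance = 5,
                           tm_method = "wallace",
                           dimer_score_threshold = 8,
                           dimer_anchored_threshold = 5,
                           platform = "capillary",
                           degraded_max_len = 300,
                           detection_threshold = 0.1,
                           balance_tolerance = 0.25,
                           balance_step = 0.1,
                           balance_bounds = c(0.1, 1.0),
                           max_step_factor = 10,
                           step_volume = 10,
                           seed = 1L) {
  structure(list(
    mass_constants = unclass(mass_constants),
    error_model = unclass(error_model),
    tm_tolerance = tm_tolerance, tm_method = tm_method,
    dimer_score_threshold = dimer_score_threshold,
    dimer_anchored_threshold = dimer_anchored_threshold,
    platform = platform, degraded_max_len = degraded_max_len,
    detection_threshold = detection_threshold,
    balance_tolerance = balance_tolerance, balance_step = balance_step,
    balance_bounds = balance_bounds,
    max_step_factor = max_step_factor, step_volume = step_volume,
    seed = as.integer(seed)
  ), class = "plexcal_config")
}

#' @rdname plexcal_config
#' @param config a `plexcal_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "plexcal_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname plexcal_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- plexcal_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(unclass(defaults), raw)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "plexcal_config")
}

# Rehydrate typed sub-objects from a config.
config_mass_constants <- function(config) {
  do.call(mass_constants, config$mass_constants)
}

config_error_model <- function(config) {
  do.call(pipetting_error_model, config$error_model)
}
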