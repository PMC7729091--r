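# Run configuration shared by the command-line pipeline. All thresholds of
# the method are collected here with their defaults and can be overridden
# from a YAML file.

#' Default run configuration
#'
#' @param task `"impairment"` or `"surgery"`.
#' @param seed Integer seed for every stochastic step.
#' @return Named list of pipeline constants: predictor completeness
#'   threshold (0.90), minimum outcome occurrences (100), detector
#'   constants (band multipliers are fixed in the feature definitions;
#'   correlation threshold 0.8, prominence fraction 0.2), bootstrap
#'   resamples B = 25, classification threshold 0.5, explanation cutoff
#'   `min_rel` = 10, and resampling unit.
#' @export
default_config <- function(task = "impairment", seed = 1) {
  list(task = task, seed = seed,
       completeness_threshold = 0.90,
       min_occurrences = 100,
       correlation_threshold = 0.8,
       prominence_frac = 0.2,
       smooth_width = 5,
       lr_rom_frac = 0.25,
       B = 25,
       classification_threshold = 0.5,
       min_rel = 10,
       resample_unit = "child",
       ntree = 500)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to [default_config].
#'
#' @param path YAML file path (or `NULL` for the defaults).
#' @param task,seed Defaults passed to [default_config].
#' @return Configuration list.
#' @export
read_config <- function(path = NULL, task = "impairment", seed = 1) {
  cfg <- default_config(task, seed)
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  utils::modifyList(cfg, user)
}

config_control <- function(cfg) {
  detector_control(correlation_threshold = cfg$correlation_threshold,
                   prominence_frac = cfg$prominence_frac,
                   smooth_width = cfg$smooth_width,
                   lr_rom_frac = cfg$lr_rom_frac)
}
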