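# Evaluation of feature detectors against a trial and a reference set.

eval_band_cond <- function(cond, trial, side, reference) {
  band <- get_band(reference, cond$stat)
  val <- eval_stat(band$spec, trial, side)
  lo <- band$mean - cond$k * band$sd
  hi <- band$mean + cond$k * band$sd
  switch(cond$dir,
         ">" = val > hi,
         "<" = val < lo,
         "<+" = val < hi,
         within = val > lo && val < hi,
         outside = val < lo || val > hi,
         stop("unknown band comparison: ", cond$dir))
}

eval_condition <- function(cond, trial, side, reference, control, depth = 0) {
  if (depth > 5) stop("feature definition recursion too deep")
  switch(cond$type,
    band = eval_band_cond(cond, trial, side, reference),
    template = {
      cv <- get_curve(trial, cond$joint, cond$plane, side)
      template_correlation(cv, get_templates(reference, cond$bank)) >
        control$correlation_threshold
    },
    feature = eval_feature(feature_registry()[[cond$name]], trial, side,
                           reference, control, depth + 1),
    expr = isTRUE(cond$fn(trial, side, reference, control)),
    stop("unknown condition type: ", cond$type)
  )
}

eval_feature <- function(def, trial, side, reference, control, depth = 0) {
  if (is.null(def)) stop("unknown feature")
  if (def$needs_pair &&
      !all(c("left", "right") %in% trial_sides(trial))) {
    warning("feature '", def$name,
            "' needs both sides; returning absent for unilateral trial")
    return(FALSE)
  }
  for (cond in def$conditions) {
    if (!eval_condition(cond, trial, side, reference, control, depth)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Detect one kinematic feature
#'
#' Evaluates the named detector (a conjunction of atomic conditions with
#' strict-inequality band semantics) on one side of a trial. Detection is
#' fully deterministic. Features that need the contralateral side return
#' absent, with a warning, on unilateral trials.
#'
#' @param name Feature name (see [feature_names]).
#' @param trial A [gait_trial].
#' @param side `"left"` or `"right"`.
#' @param reference A `reference_set` from [build_reference].
#' @param control Detector constants, see [detector_control].
#' @return Logical: `TRUE` when the feature is present.
#' @export
detect_feature <- function(name, trial, side, reference,
                           control = detector_control()) {
  def <- feature_registry()[[name]]
  if (is.null(def)) stop("unknown feature: ", name)
  eval_feature(def, trial, side, reference, control)
}

#' Extract the full binary feature vector of a trial
#'
#' Evaluates all 49 built-in detectors on each available side. Bilateral
#' features (left/right pelvic difference features) are computed from the
#' pair and assigned to both sides.
#'
#' @param trial A [gait_trial].
#' @param reference A `reference_set`.
#' @param control Detector constants, see [detector_control].
#' @return Data frame with one row per side: columns `side` plus one 0/1
#'   column per feature (registry order).
#' @export
extract_features <- function(trial, reference, control = detector_control()) {
  reg <- feature_registry(include_custom = FALSE)
  sides <- trial_sides(trial)
  flags <- vapply(sides, function(s) {
    vapply(reg, function(def)
      as.integer(eval_feature(def, trial, s, reference, control)), integer(1))
  }, integer(length(reg)))
  res <- as.data.frame(t(flags))
  names(res) <- names(reg)
  cbind(data.frame(side = sides, stringsAsFactors = FALSE), res)
}

#' Register a custom feature detector
#'
#' Builds a detector from a declarative definition using the same condition
#' vocabulary as the built-ins (band comparisons, template correlations,
#' references to other features, or arbitrary pure predicate functions) and
#' registers it so [detect_feature] can evaluate it by name.
#'
#' @param name Detector name. Must not shadow a built-in unless
#'   `override = TRUE`.
#' @param joint,plane Curve the detector reads (metadata).
#' @param conditions List of conditions; each a list with `type` in
#'   `"band"`, `"template"`, `"feature"`, `"expr"` and the fields the
#'   corresponding built-in conditions use (`stat`, `dir`, `k`; `bank`;
#'   `name`; `fn`).
#' @param bilateral Does the detector need both sides?
#' @param reference Optional `reference_set` used to validate that the
#'   referenced bands and template banks exist.
#' @param override Allow replacing a built-in definition.
#' @return The registered definition, invisibly.
#' @export
make_custom_detector <- function(name, joint, plane, conditions,
                                 bilateral = FALSE, reference = NULL,
                                 override = FALSE) {
  if (length(conditions) == 0) stop("empty predicate: no conditions given")
  if (name %in% feature_names() && !override) {
    stop("'", name, "' shadows a built-in detector; use override = TRUE")
  }
  known_stats <- names(stat_registry())
  for (cond in conditions) {
    if (is.null(cond$type)) stop("condition without a type")
    if (cond$type == "band") {
      if (!cond$stat %in% known_stats) {
        stop("unknown band statistic: ", cond$stat)
      }
      if (!cond$dir %in% c(">", "<", "<+", "within", "outside")) {
        stop("unknown band comparison: ", cond$dir)
      }
      if (!is.null(reference)) get_band(reference, cond$stat)
    } else if (cond$type == "template") {
      if (!is.null(reference)) get_templates(reference, cond$bank)
    } else if (cond$type == "feature") {
      if (!cond$name %in% names(feature_registry())) {
        stop("unknown feature referenced: ", cond$name)
      }
    } else if (cond$type == "expr") {
      if (!is.function(cond$fn)) stop("expr condition needs a function")
    } else {
      stop("unknown condition type: ", cond$type)
    }
  }
  def <- feat(name, joint, plane, conditions, bilateral = bilateral)
  if (is.null(.registry_env$custom)) .registry_env$custom <- list()
  .registry_env$custom[[name]] <- def
  invisible(def)
}

#' Remove a custom detector
#' @param name Name previously registered via [make_custom_detector].
#' @export
remove_custom_detector <- function(name) {
  .registry_env$custom[[name]] <- NULL
  invisible(NULL)
}
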