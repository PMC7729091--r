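# The registry of 49 binary kinematic feature detectors. Each detector is a
# conjunction of atomic conditions over one joint/plane curve (plus, for a
# few features, the contralateral curve), compared against reference bands
# with strict-inequality semantics: "> k SD" means statistic > mean + k*SD,
# "< k SD" means statistic < mean - k*SD; boundary equality counts as
# absent.

band_cond <- function(stat, dir, k) {
  list(type = "band", stat = stat, dir = dir, k = k)
}
template_cond <- function(joint, plane, bank) {
  list(type = "template", joint = joint, plane = plane, bank = bank)
}
feature_cond <- function(name) list(type = "feature", name = name)
expr_cond <- function(fn, desc) list(type = "expr", fn = fn, desc = desc)

feat <- function(name, structure, plane, conditions, bilateral = FALSE,
                 needs_pair = bilateral) {
  list(name = name, structure = structure, plane = plane,
       conditions = conditions, bilateral = bilateral,
       needs_pair = needs_pair)
}

#' Tuning constants of the feature detectors
#'
#' @param correlation_threshold Minimum template correlation (default 0.8).
#' @param prominence_frac Peak/pit prominence as a fraction of full-cycle
#'   ROM (default 0.2).
#' @param smooth_width Moving-average width for bump counting (default 5).
#' @param lr_rom_frac The double-bump left/right-agreement bound: the mean
#'   absolute left-right difference must be below this fraction of the mean
#'   of the two sides' ROM (default 0.25).
#' @return A named list of detector constants.
#' @export
detector_control <- function(correlation_threshold = 0.8,
                             prominence_frac = 0.2, smooth_width = 5L,
                             lr_rom_frac = 0.25) {
  list(correlation_threshold = correlation_threshold,
       prominence_frac = prominence_frac,
       smooth_width = as.integer(smooth_width), lr_rom_frac = lr_rom_frac)
}

# pair-level double-bump agreement clause: mean |L-R| < frac * mean(ROM_L, ROM_R)
double_bump_lr_clause <- function(trial, control) {
  d <- lr_difference(trial, "pelvis", "sagittal", "mean_abs_diff")
  rl <- rom(get_curve(trial, "pelvis", "sagittal", "left"))
  rr <- rom(get_curve(trial, "pelvis", "sagittal", "right"))
  d < control$lr_rom_frac * mean(c(rl, rr))
}

double_bump_shape <- function(trial, side, reference, control) {
  cv <- get_curve(trial, "pelvis", "sagittal", side)
  bump_count(cv, control$prominence_frac, control$smooth_width) == 2L &&
    template_correlation(cv, get_templates(reference, "double_bump")) >
      control$correlation_threshold &&
    double_bump_lr_clause(trial, control)
}

built_in_features <- function() {
  fs <- list(
    # -- Pelvis / sagittal -------------------------------------------------
    feat("Increased ROM (double bump)", "pelvis", "sagittal", list(
      band_cond("pelvis_sagittal_rom_full", ">", 2),
      expr_cond(function(trial, side, reference, control)
        double_bump_shape(trial, side, reference, control),
        "double-bump shape (period 2, template correlation, L/R agreement)")
    ), needs_pair = TRUE),
    feat("Decreased Pelvic Tilt", "pelvis", "sagittal", list(
      band_cond("pelvis_sagittal_mean_full", "<", 1)
    )),
    feat("Decreased Pelvic Tilt + Increased ROM", "pelvis", "sagittal", list(
      feature_cond("Decreased Pelvic Tilt"),
      band_cond("pelvis_sagittal_rom_full", ">", 2)
    )),
    feat("Increased Pelvic Tilt", "pelvis", "sagittal", list(
      band_cond("pelvis_sagittal_mean_full", ">", 1)
    )),
    feat("Increased Pelvic Tilt + Increased ROM", "pelvis", "sagittal", list(
      feature_cond("Increased Pelvic Tilt"),
      band_cond("pelvis_sagittal_rom_full", ">", 2)
    )),
    feat("Unilateral Bump", "pelvis", "sagittal", list(
      band_cond("pelvis_sagittal_rom_full", ">", 2),
      expr_cond(function(trial, side, reference, control)
        !double_bump_shape(trial, side, reference, control),
        "not the double-bump shape")
    ), needs_pair = TRUE),
    # -- Pelvis / coronal --------------------------------------------------
    feat("Increased Pelvic ROM", "pelvis", "coronal", list(
      band_cond("pelvis_coronal_rom_full", ">", 2)
    )),
    feat("Pelvic Elevation/Depression", "pelvis", "coronal", list(
      band_cond("pelvis_coronal_lrdiff", "outside", 1)
    ), bilateral = TRUE),
    # -- Pelvis / transverse -----------------------------------------------
    feat("Increased Pelvic Rotation ROM", "pelvis", "transverse", list(
      band_cond("pelvis_transverse_rom_full", ">", 2)
    )),
    feat("Pelvic Pro/Retraction", "pelvis", "transverse", list(
      band_cond("pelvis_transverse_lrdiff", "outside", 1)
    ), bilateral = TRUE),
    feat("Reversed ROM", "pelvis", "transverse", list(
      template_cond("pelvis", "transverse", "reversed_rom")
    )),
    # -- Hip / sagittal ----------------------------------------------------
    feat("Decreased Hip Flexion at Initial Contact", "hip", "sagittal", list(
      band_cond("hip_sagittal_value_0", "<", 2)
    )),
    feat("Hip Extension Deficit", "hip", "sagittal", list(
      band_cond("hip_sagittal_mean_stance", ">", 1),
      band_cond("hip_sagittal_rom_full", "<", 2)
    )),
    feat("Hip Hyper-Flexion", "hip", "sagittal", list(
      band_cond("hip_sagittal_mean_stance", "within", 1),
      band_cond("hip_sagittal_peak_swing", ">", 2)
    )),
    feat("Increased Hip Extension at Mid Stance", "hip", "sagittal", list(
      band_cond("hip_sagittal_mean_20_45", "<", 1)
    )),
    feat("Increased Hip Flexion", "hip", "sagittal", list(
      band_cond("hip_sagittal_mean_stance", ">", 1),
      expr_cond(function(trial, side, reference, control)
        min(get_curve(trial, "hip", "sagittal", side)$values) > 0,
        "all angles > 0")
    )),
    feat("Increased Hip Flexion + Decreased ROM", "hip", "sagittal", list(
      feature_cond("Increased Hip Flexion"),
      band_cond("hip_sagittal_rom_full", "<", 2)
    )),
    # -- Hip / coronal -----------------------------------------------------
    feat("Excessive Hip Abduction", "hip", "coronal", list(
      band_cond("hip_coronal_mean_stance", "<", 1),
      band_cond("hip_coronal_mean_swing", "<", 1)
    )),
    feat("Excessive Hip Abduction in Swing", "hip", "coronal", list(
      band_cond("hip_coronal_mean_swing", "<", 1)
    )),
    feat("Excessive Hip Adduction", "hip", "coronal", list(
      band_cond("hip_coronal_mean_stance", ">", 1),
      band_cond("hip_coronal_mean_swing", ">", 1)
    )),
    feat("Hip Adduction in Stance", "hip", "coronal", list(
      band_cond("hip_coronal_mean_stance", ">", 1)
    )),
    # -- Hip / transverse --------------------------------------------------
    feat("Hip External Rotation", "hip", "transverse", list(
      band_cond("hip_transverse_mean_full", "<", 1)
    )),
    feat("Hip Internal Rotation", "hip", "transverse", list(
      band_cond("hip_transverse_mean_full", ">", 1)
    )),
    feat("Increased Hip Internal Rotation at Late Stance", "hip",
         "transverse", list(
      band_cond("hip_transverse_mean_40_60", ">", 1),
      expr_cond(function(trial, side, reference, control) {
        cv <- get_curve(trial, "hip", "transverse", side)
        window_peak(cv, 0:100, control$prominence_frac)$t < 70
      }, "peak occurs before t = 70"),
      expr_cond(function(trial, side, reference, control) {
        cv <- get_curve(trial, "hip", "transverse", side)
        is.null(extremum(cv, 20:80, "pit", control$prominence_frac))
      }, "no pit in t in [20, 80]")
    )),
    # -- Knee / sagittal ---------------------------------------------------
    feat("Reduced Flexion at Loading", "knee", "sagittal", list(
      band_cond("knee_sagittal_mean_0_20", "<", 1)
    )),
    feat("Decreased Peak Knee Flexion", "knee", "sagittal", list(
      band_cond("knee_sagittal_peak_swing", "<", 2)
    )),
    feat("Delayed + Decreased Peak Knee Flexion", "knee", "sagittal", list(
      feature_cond("Delayed Peak Knee Flexion"),
      feature_cond("Decreased Peak Knee Flexion")
    )),
    feat("Delayed + Increased Peak Knee Flexion", "knee", "sagittal", list(
      feature_cond("Delayed Peak Knee Flexion"),
      band_cond("knee_sagittal_peak_swing", ">", 2)
    )),
    feat("Delayed Peak Knee Flexion", "knee", "sagittal", list(
      expr_cond(function(trial, side, reference, control) {
        cv <- get_curve(trial, "knee", "sagittal", side)
        sw <- stance_swing_windows(trial, side)$swing
        window_peak(cv, sw, control$prominence_frac)$t > 75
      }, "swing peak occurs after t = 75")
    )),
    feat("Knee Flexion in Mid Stance", "knee", "sagittal", list(
      band_cond("knee_sagittal_mean_20_45", ">", 1)
    )),
    feat("Knee Hyperextension", "knee", "sagittal", list(
      band_cond("knee_sagittal_mean_20_45", "<", 1)
    )),
    feat("Increased Flexion at Initial Contact", "knee", "sagittal", list(
      band_cond("knee_sagittal_value_0", ">", 2)
    )),
    feat("Increased Flexion at Initial Contact + Early Knee Extension",
         "knee", "sagittal", list(
      feature_cond("Increased Flexion at Initial Contact"),
      expr_cond(function(trial, side, reference, control) {
        cv <- get_curve(trial, "knee", "sagittal", side)
        pit <- window_pit(cv, win(1, 50), control$prominence_frac)
        pit$t < 25 && (value_at(cv, 0) - pit$value) > 10
      }, "pit before t = 25 with initial-contact drop > 10 deg"),
      # Table rule: min angle in [10,25] below mean + 1 SD (upper bound)
      band_cond("knee_sagittal_min_10_25", "<+", 1)
    )),
    feat("Increased Peak Knee Flexion", "knee", "sagittal", list(
      band_cond("knee_sagittal_peak_swing", ">", 2)
    )),
    # -- Ankle / sagittal --------------------------------------------------
    feat("Reduced Dorsiflexion", "ankle", "sagittal", list(
      band_cond("ankle_sagittal_mean_0_50", "<", 1)
    )),
    feat("Descending 2nd Rocker", "ankle", "sagittal", list(
      expr_cond(function(trial, side, reference, control) {
        cv <- get_curve(trial, "ankle", "sagittal", side)
        (value_at(cv, 45) - value_at(cv, 20)) < -5 && value_at(cv, 45) < 0
      }, "angle(45) - angle(20) < -5 and angle(45) < 0")
    )),
    feat("Dorsiflexion in Swing", "ankle", "sagittal", list(
      band_cond("ankle_sagittal_mean_swing", ">", 1)
    )),
    feat("Foot Drop", "ankle", "sagittal", list(
      band_cond("ankle_sagittal_mean_80_100", "<", 1)
    )),
    feat("Horizontal 2nd Rocker", "ankle", "sagittal", list(
      expr_cond(function(trial, side, reference, control) {
        cv <- get_curve(trial, "ankle", "sagittal", side)
        rom(cv, win(20, 45)) < 5 && abs(slope(cv, win(20, 45))) < 0.1 &&
          value_at(cv, 45) < 0
      }, "ROM[20,45] < 5, |slope| < 0.1, angle(45) < 0")
    )),
    feat("Increased Dorsiflexion", "ankle", "sagittal", list(
      band_cond("ankle_sagittal_mean_20_45", ">", 1)
    )),
    feat("Increased Max. Dorsiflexion", "ankle", "sagittal", list(
      band_cond("ankle_sagittal_max_stance", ">", 2)
    )),
    feat("Increased Plantarflexion", "ankle", "sagittal", list(
      band_cond("ankle_sagittal_mean_20_45", "<", 1)
    )),
    feat("Insufficient Pre-positioning", "ankle", "sagittal", list(
      band_cond("ankle_sagittal_value_100", ">", 2)
    )),
    feat("No 1st Rocker", "ankle", "sagittal", list(
      expr_cond(function(trial, side, reference, control) {
        cv <- get_curve(trial, "ankle", "sagittal", side)
        value_at(cv, 1) > value_at(cv, 0)
      }, "angle at t = 1 > angle at t = 0")
    )),
    feat("Short 2nd Rocker", "ankle", "sagittal", list(
      expr_cond(function(trial, side, reference, control) {
        cv <- get_curve(trial, "ankle", "sagittal", side)
        !is.null(extremum(cv, 0:20, "peak", control$prominence_frac)) &&
          slope(cv, win(20, 45)) < 0
      }, "peak exists in t in [0,20] and slope[20,45] < 0"),
      template_cond("ankle", "sagittal", "short_2nd_rocker")
    )),
    # -- Ankle / transverse ------------------------------------------------
    feat("Ankle Internal Rotation", "ankle", "transverse", list(
      band_cond("ankle_transverse_mean_stance", ">", 1)
    )),
    # -- Foot progression / transverse ------------------------------------
    feat("External Foot Progression (Wave) in Swing only",
         "foot_progression", "transverse", list(
      band_cond("foot_progression_transverse_rom_swing", ">", 2),
      template_cond("foot_progression", "transverse", "external_fp_wave")
    )),
    feat("In-toe", "foot_progression", "transverse", list(
      band_cond("foot_progression_transverse_mean_stance", ">", 1)
    )),
    feat("Out-toe", "foot_progression", "transverse", list(
      band_cond("foot_progression_transverse_mean_stance", "<", 1)
    ))
  )
  names(fs) <- vapply(fs, `[[`, character(1), "name")
  fs
}

# environment holding built-ins (cached) and user-registered detectors
.registry_env <- new.env(parent = emptyenv())

#' The feature detector registry
#'
#' @param include_custom Include detectors registered through
#'   [make_custom_detector].
#' @return Named list of feature definitions (49 built-ins, plus customs).
#' @export
feature_registry <- function(include_custom = TRUE) {
  if (is.null(.registry_env$built_in)) {
    .registry_env$built_in <- built_in_features()
  }
  reg <- .registry_env$built_in
  if (include_custom && !is.null(.registry_env$custom)) {
    for (nm in names(.registry_env$custom)) {
      reg[[nm]] <- .registry_env$custom[[nm]]
    }
  }
  reg
}

#' Names of the built-in features
#' @return Character vector of length 49, in registry order.
#' @export
feature_names <- function() names(feature_registry(include_custom = FALSE))
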