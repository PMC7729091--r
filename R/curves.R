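# Curve and trial containers. A gait cycle is indexed by t = 0..100 (% of
# cycle); every curve holds exactly 101 angle samples in degrees.

#' Joint/plane combinations carried by a gait trial
#'
#' The eleven joint-by-plane angle curves used for feature extraction:
#' pelvis and hip in all three planes, knee in all three planes (knee
#' coronal/transverse are stored but no built-in detector reads them),
#' ankle sagittal and transverse, and foot progression transverse.
#'
#' Sign conventions follow the clinical (Plug-in-Gait) convention: anterior
#' pelvic tilt, hip flexion, hip adduction, hip internal rotation, knee
#' flexion, ankle dorsiflexion and internal foot progression are positive.
#'
#' @return A data frame with columns `joint` and `plane`, one row per valid
#'   combination.
#' @export
curve_combinations <- function() {
  data.frame(
    joint = c(rep("pelvis", 3), rep("hip", 3), rep("knee", 3),
              "ankle", "ankle", "foot_progression"),
    plane = c(rep(c("sagittal", "coronal", "transverse"), 3),
              "sagittal", "transverse", "transverse"),
    stringsAsFactors = FALSE
  )
}

# curves every side must provide before feature extraction is possible
mandatory_combinations <- function() {
  data.frame(
    joint = c("pelvis", "pelvis", "pelvis", "hip", "hip", "hip",
              "knee", "ankle", "ankle", "foot_progression"),
    plane = c("sagittal", "coronal", "transverse",
              "sagittal", "coronal", "transverse",
              "sagittal", "sagittal", "transverse", "transverse"),
    stringsAsFactors = FALSE
  )
}

#' Construct a single joint-angle curve
#'
#' @param joint One of `"pelvis"`, `"hip"`, `"knee"`, `"ankle"`,
#'   `"foot_progression"`.
#' @param plane One of `"sagittal"`, `"coronal"`, `"transverse"`.
#' @param side `"left"` or `"right"`.
#' @param values Numeric vector of 101 finite angles (degrees), one per
#'   percent of the gait cycle, t = 0..100.
#' @return An object of class `gait_curve`.
#' @export
gait_curve <- function(joint, plane, side, values) {
  joint <- match.arg(joint, c("pelvis", "hip", "knee", "ankle",
                              "foot_progression"))
  plane <- match.arg(plane, c("sagittal", "coronal", "transverse"))
  side <- match.arg(side, c("left", "right"))
  combos <- curve_combinations()
  if (!any(combos$joint == joint & combos$plane == plane)) {
    stop("invalid joint/plane combination: ", joint, "/", plane)
  }
  values <- as.numeric(values)
  if (length(values) != 101L) {
    stop("a gait curve must hold exactly 101 samples, got ", length(values))
  }
  if (!all(is.finite(values))) stop("curve values must all be finite")
  structure(list(joint = joint, plane = plane, side = side, values = values),
            class = "gait_curve")
}

#' @export
print.gait_curve <- function(x, ...) {
  cat(sprintf("<gait_curve> %s/%s/%s  range [%.2f, %.2f] deg\n",
              x$joint, x$plane, x$side, min(x$values), max(x$values)))
  invisible(x)
}

curve_key <- function(joint, plane, side) paste(joint, plane, side, sep = "_")

#' Construct a gait trial
#'
#' A trial bundles the per-side curves of one walking trial together with the
#' ipsilateral foot-off timing (% of gait cycle, strictly inside (0, 100))
#' and a group tag.
#'
#' @param trial_id,subject_id Identifiers (character scalars).
#' @param curves A list of [gait_curve] objects.
#' @param foot_off Named numeric vector with elements `left` and/or `right`,
#'   each strictly between 0 and 100.
#' @param group `"patient"` or `"typically_developing"`.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(trial_id, subject_id, curves, foot_off,
                       group = c("patient", "typically_developing")) {
  group <- match.arg(group)
  stopifnot(is.list(curves), length(curves) >= 1)
  for (cv in curves) {
    if (!inherits(cv, "gait_curve")) stop("curves must be gait_curve objects")
  }
  names(curves) <- vapply(curves, function(cv)
    curve_key(cv$joint, cv$plane, cv$side), character(1))
  if (anyDuplicated(names(curves))) {
    stop("duplicate curve: ", names(curves)[duplicated(names(curves))][1])
  }
  sides <- unique(vapply(curves, function(cv) cv$side, character(1)))
  foot_off <- unlist(foot_off)
  for (s in sides) {
    if (is.na(foot_off[s]) || is.null(foot_off[s])) {
      stop("foot_off missing for side ", s)
    }
    if (foot_off[[s]] <= 0 || foot_off[[s]] >= 100) {
      stop("foot_off must lie strictly between 0 and 100")
    }
    mand <- mandatory_combinations()
    for (i in seq_len(nrow(mand))) {
      key <- curve_key(mand$joint[i], mand$plane[i], s)
      if (!key %in% names(curves)) {
        stop("incomplete trial: ", mand$joint[i], "/", mand$plane[i], "/", s)
      }
    }
  }
  structure(list(trial_id = as.character(trial_id),
                 subject_id = as.character(subject_id),
                 curves = curves, foot_off = foot_off[sides], group = group),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %s (subject %s, %s): %d curves, sides %s\n",
              x$trial_id, x$subject_id, x$group, length(x$curves),
              paste(trial_sides(x), collapse = "/")))
  invisible(x)
}

#' Sides present in a trial
#' @param trial A [gait_trial].
#' @return Character vector, subset of `c("left", "right")`.
#' @export
trial_sides <- function(trial) {
  intersect(c("left", "right"),
            unique(vapply(trial$curves, function(cv) cv$side, character(1))))
}

#' Fetch one curve from a trial
#' @param trial A [gait_trial].
#' @param joint,plane,side Curve selector.
#' @return The [gait_curve], or an error if absent.
#' @export
get_curve <- function(trial, joint, plane, side) {
  key <- curve_key(joint, plane, side)
  cv <- trial$curves[[key]]
  if (is.null(cv)) stop("trial has no curve ", joint, "/", plane, "/", side)
  cv
}

curve_values <- function(x) {
  if (inherits(x, "gait_curve")) x$values else as.numeric(x)
}

#' Resample an angle series onto the 101-point gait-cycle grid
#'
#' Linear interpolation of an arbitrary-length series onto a uniform grid of
#' 101 samples (t = 0..100% of the cycle). Endpoints are preserved exactly;
#' length-101 input is returned unchanged.
#'
#' @param series Numeric vector, length at least 2, all finite.
#' @return Numeric vector of length 101.
#' @export
resample_to_cycle <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2L) stop("cannot resample a series of length < 2")
  if (!all(is.finite(series))) stop("series values must all be finite")
  if (n == 101L) return(series)
  stats::approx(x = seq(0, 100, length.out = n), y = series,
                xout = 0:100, method = "linear")$y
}

#' Stance and swing sample windows of a trial side
#'
#' Stance covers samples t = 0..floor(foot_off); swing the remainder of the
#' cycle. The two windows are disjoint and jointly cover t = 0..100.
#'
#' @param trial A [gait_trial].
#' @param side `"left"` or `"right"`.
#' @return A list with integer vectors `stance` and `swing` (values of t).
#' @export
stance_swing_windows <- function(trial, side) {
  side <- match.arg(side, c("left", "right"))
  fo <- trial$foot_off[[side]]
  if (is.null(fo) || is.na(fo)) stop("foot_off not defined for side ", side)
  cut <- floor(fo)
  list(stance = 0:cut, swing = seq.int(cut + 1L, 100L))
}
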