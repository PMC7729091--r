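# Primitive curve statistics used by the feature detectors. All windows are
# inclusive integer sets of t-values on the 0..100 gait-cycle grid.

check_window <- function(window) {
  window <- as.integer(window)
  if (length(window) == 0) stop("empty window")
  if (any(window < 0 | window > 100)) stop("window values must lie in 0..100")
  window
}

win_idx <- function(window) check_window(window) + 1L

#' Window helper
#'
#' @param a,b Inclusive bounds on the t grid (0..100).
#' @return Integer vector of t values `a..b`.
#' @export
win <- function(a, b) {
  stopifnot(a >= 0, b <= 100, a <= b)
  seq.int(a, b)
}

#' Range of motion over a window
#'
#' Max minus min of the angle over an inclusive integer window; always
#' non-negative.
#'
#' @param curve A [gait_curve] or numeric vector of 101 angles.
#' @param window Integer vector of t values (default: full cycle).
#' @return Degrees.
#' @export
rom <- function(curve, window = 0:100) {
  v <- curve_values(curve)[win_idx(window)]
  max(v) - min(v)
}

#' Mean angle over a window
#' @inheritParams rom
#' @return Degrees.
#' @export
window_mean <- function(curve, window = 0:100) {
  mean(curve_values(curve)[win_idx(window)])
}

#' Angle at one sample of the gait cycle
#' @param curve A [gait_curve] or numeric vector of 101 angles.
#' @param t Integer in 0..100.
#' @return Degrees.
#' @export
value_at <- function(curve, t) {
  if (length(t) != 1 || t < 0 || t > 100) stop("t must be a single value in 0..100")
  curve_values(curve)[as.integer(t) + 1L]
}

#' Least-squares slope over a window
#'
#' Slope of the simple linear regression of angle on t over the window, in
#' degrees per percent of the gait cycle.
#'
#' @inheritParams rom
#' @return Degrees per % gait cycle.
#' @export
slope <- function(curve, window) {
  window <- check_window(window)
  if (length(window) < 2) stop("slope needs a window of length >= 2")
  v <- curve_values(curve)[window + 1L]
  t <- as.numeric(window)
  sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
}

# prominence of a local extremum at index i (1-based) of v; for pits pass -v
peak_prominence <- function(v, i) {
  n <- length(v)
  left_min <- v[i]
  j <- i - 1L
  while (j >= 1L && v[j] <= v[i]) {
    left_min <- min(left_min, v[j])
    j <- j - 1L
  }
  if (j < 1L) left_min <- min(v[seq_len(i)])
  right_min <- v[i]
  j <- i + 1L
  while (j <= n && v[j] <= v[i]) {
    right_min <- min(right_min, v[j])
    j <- j + 1L
  }
  if (j > n) right_min <- min(v[i:n])
  v[i] - max(left_min, right_min)
}

#' Locate a qualifying peak or pit in a window
#'
#' A peak is a sample that is a strict interior local maximum of the
#' full-cycle curve whose prominence is at least `prominence_frac` times the
#' full-cycle range of motion (a pit is the mirror image). Among qualifying
#' samples inside the window, the one with the most extreme value is
#' returned; ties go to the earliest t.
#'
#' @inheritParams rom
#' @param kind `"peak"` or `"pit"`.
#' @param prominence_frac Minimum prominence as a fraction of full-cycle ROM.
#' @return A list with elements `t` and `value`, or `NULL` if no sample
#'   qualifies.
#' @export
extremum <- function(curve, window = 0:100, kind = c("peak", "pit"),
                     prominence_frac = 0.2) {
  kind <- match.arg(kind)
  window <- check_window(window)
  v <- curve_values(curve)
  if (kind == "pit") v <- -v
  full_rom <- max(v) - min(v)
  if (full_rom <= 0) return(NULL)
  cand <- which(diff(sign(diff(v))) < 0) + 1L     # strict interior local maxima
  cand <- cand[v[cand] > v[cand - 1L] & v[cand] > v[cand + 1L]]
  cand <- cand[(cand - 1L) %in% window]
  if (length(cand) == 0) return(NULL)
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  cand <- cand[prom >= prominence_frac * full_rom]
  if (length(cand) == 0) return(NULL)
  best <- cand[which.max(v[cand])]                # earliest wins ties
  val <- v[best]
  if (kind == "pit") val <- -val
  list(t = best - 1L, value = val)
}

#' Swing-phase peak with global-maximum fallback
#'
#' Returns the qualifying local peak ([extremum]) in the window; if none
#' exists, falls back to the global maximum over the window (a clinician
#' always identifies some peak). Used by the peak-based knee and hip
#' detectors and the corresponding reference bands.
#'
#' @inheritParams extremum
#' @return A list with `t`, `value` and `qualified` (logical: `TRUE` when a
#'   prominent local peak was found, `FALSE` for the fallback).
#' @export
window_peak <- function(curve, window, prominence_frac = 0.2) {
  ex <- extremum(curve, window, "peak", prominence_frac)
  if (!is.null(ex)) return(c(ex, list(qualified = TRUE)))
  idx <- win_idx(window)
  v <- curve_values(curve)[idx]
  i <- which.max(v)
  list(t = check_window(window)[i], value = v[i], qualified = FALSE)
}

# pit with global-minimum fallback over the window
window_pit <- function(curve, window, prominence_frac = 0.2) {
  ex <- extremum(curve, window, "pit", prominence_frac)
  if (!is.null(ex)) return(c(ex, list(qualified = TRUE)))
  idx <- win_idx(window)
  v <- curve_values(curve)[idx]
  i <- which.min(v)
  list(t = check_window(window)[i], value = v[i], qualified = FALSE)
}

# centered moving average, width samples (odd), shrinking at the edges
smooth_ma <- function(v, width = 5L) {
  half <- (as.integer(width) - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Count prominent bumps over the gait cycle
#'
#' Number of qualifying peaks (per [extremum], after light smoothing with a
#' centered moving average) over the full cycle. A curve with "period 2" --
#' the pelvic double-bump pattern -- has a bump count of 2.
#'
#' @inheritParams extremum
#' @param smooth_width Width (samples) of the centered moving average applied
#'   before peak detection.
#' @return Integer count.
#' @export
bump_count <- function(curve, prominence_frac = 0.2, smooth_width = 5L) {
  v <- smooth_ma(curve_values(curve), smooth_width)
  full_rom <- max(v) - min(v)
  if (full_rom <= 0) return(0L)
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  cand <- cand[v[cand] > v[cand - 1L] & v[cand] > v[cand + 1L]]
  if (length(cand) == 0) return(0L)
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  sum(prom >= prominence_frac * full_rom)
}

#' Maximum Pearson correlation with a bank of template curves
#'
#' The curve is compared with each 101-sample template; the maximum Pearson
#' correlation is returned. A zero-variance curve or template contributes 0.
#'
#' @inheritParams rom
#' @param templates A list of numeric vectors (101 samples each).
#' @return Correlation in \[-1, 1\].
#' @export
template_correlation <- function(curve, templates) {
  if (length(templates) == 0) stop("empty template list")
  v <- curve_values(curve)
  rs <- vapply(templates, function(tp) {
    tp <- curve_values(tp)
    if (stats::sd(v) == 0 || stats::sd(tp) == 0) return(0)
    stats::cor(v, tp)
  }, numeric(1))
  max(rs)
}

#' Left-right curve difference
#'
#' Mean over the gait cycle of the signed (left minus right) or absolute
#' pointwise difference between the two sides of one joint/plane.
#'
#' @param trial A [gait_trial] with both sides present.
#' @param joint,plane Curve selector.
#' @param kind `"signed_mean_diff"` or `"mean_abs_diff"`.
#' @return Degrees.
#' @export
lr_difference <- function(trial, joint, plane,
                          kind = c("signed_mean_diff", "mean_abs_diff")) {
  kind <- match.arg(kind)
  sides <- trial_sides(trial)
  if (!all(c("left", "right") %in% sides)) {
    stop("lr_difference needs both sides present")
  }
  l <- get_curve(trial, joint, plane, "left")$values
  r <- get_curve(trial, joint, plane, "right")$values
  if (kind == "signed_mean_diff") mean(l - r) else mean(abs(l - r))
}
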