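# Proper scoring metrics. The weighted Brier score weights each record by
# the reciprocal of its true class frequency and normalizes by the weight
# sum, so a constant-0.5 predictor scores 0.25 weighted or not, and any
# admissible model must score below 0.25.

check_po <- function(p, o) {
  if (length(p) != length(o)) stop("predictions and outcomes differ in length")
  if (length(p) < 1) stop("empty input")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(o %in% c(0, 1))) stop("outcomes must be 0/1")
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes: the mean-squared-error equivalent for binary classification,
#' and a proper scoring rule.
#'
#' @param p Predicted probabilities in \[0, 1\].
#' @param o Observed classes (0/1).
#' @return Score in \[0, 1\]; lower is better.
#' @export
brier <- function(p, o) {
  check_po(p, o)
  mean((p - o)^2)
}

#' Weighted Brier score
#'
#' Brier score with each term weighted by the reciprocal of its true class
#' frequency (class count / N) and normalized by the total weight, so
#' errors in the minority class are penalized more heavily under class
#' imbalance.
#'
#' @inheritParams brier
#' @return Score in \[0, 1\]; lower is better.
#' @export
weighted_brier <- function(p, o) {
  check_po(p, o)
  n1 <- sum(o == 1)
  n0 <- sum(o == 0)
  if (n1 == 0 || n0 == 0) {
    stop("weights undefined: both classes must be present")
  }
  n <- length(o)
  w <- ifelse(o == 1, n / n1, n / n0)
  sum(w * (p - o)^2) / sum(w)
}

#' Threshold classification metrics
#'
#' Misclassification rate, sensitivity and specificity of the class rule
#' `p >= threshold`.
#'
#' @inheritParams brier
#' @param threshold Classification threshold (default 0.5).
#' @return Named list with `misclassification`, `sensitivity`,
#'   `specificity`.
#' @export
binary_metrics <- function(p, o, threshold = 0.5) {
  check_po(p, o)
  if (sum(o == 1) == 0 || sum(o == 0) == 0) {
    stop("sensitivity/specificity undefined: both classes must be present")
  }
  pred <- as.integer(p >= threshold)
  list(misclassification = mean(pred != o),
       sensitivity = sum(pred == 1 & o == 1) / sum(o == 1),
       specificity = sum(pred == 0 & o == 0) / sum(o == 0))
}
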