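# Isotonic probability calibration on pooled out-of-bag predictions. The
# isotonic regression is itself trained under an out-of-bag bootstrap
# scheme: B2 bootstrap isotonic fits on the pooled (prediction, class)
# pairs, averaged pointwise (an average of monotone maps is monotone) and
# clipped to [0, 1].

#' Fit an isotonic calibration map
#'
#' @param p Pooled out-of-bag predicted probabilities.
#' @param o Matching observed classes (0/1); both classes must be present.
#' @param B2 Number of bootstrap isotonic fits (default 25).
#' @param seed Integer seed.
#' @return A `calibration_map`: monotone non-decreasing step/interpolated
#'   map on \[0, 1\] with range inside \[0, 1\].
#' @export
calibrate_isotonic <- function(p, o, B2 = 25, seed = 1) {
  check_po(p, o)
  if (sum(o == 1) == 0 || sum(o == 0) == 0) {
    stop("calibration needs both classes present")
  }
  grid <- seq(0, 1, length.out = 201)
  n <- length(p)
  run_seeded(seed, {
    acc <- matrix(NA_real_, B2, length(grid))
    for (b in seq_len(B2)) {
      idx <- sample.int(n, n, replace = TRUE)
      acc[b, ] <- eval_isotonic(p[idx], o[idx], grid)
    }
    vals <- pmin(1, pmax(0, colMeans(acc)))
    structure(list(grid = grid, values = cummax(vals)),
              class = "calibration_map")
  })
}

# single isotonic fit evaluated on a grid (linear interpolation between
# knots, tied predictions averaged, clamped outside the observed range)
eval_isotonic <- function(p, o, grid) {
  ord <- order(p)
  iso <- stats::isoreg(p[ord], o[ord])
  if (iso$x[1] == iso$x[length(iso$x)]) {
    return(rep(mean(iso$yf), length(grid)))
  }
  stats::approx(iso$x, iso$yf, xout = grid, rule = 2, ties = mean)$y
}

#' @export
predict.calibration_map <- function(object, newdata, ...) {
  pmin(1, pmax(0, stats::approx(object$grid, object$values, xout = newdata,
                                rule = 2)$y))
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("<calibration_map> isotonic, range [%.3f, %.3f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Calibrate an outcome model
#'
#' Attaches an isotonic calibration map, fitted on the model's pooled
#' out-of-bag predictions, so the reported probability is the calibrated
#' one.
#'
#' @param model An `outcome_model` from [tune_and_train].
#' @param B2 Bootstrap isotonic fits (default 25).
#' @param seed Integer seed (default: the model's seed).
#' @return The model with a `calibration` component.
#' @export
calibrate_model <- function(model, B2 = 25, seed = NULL) {
  if (is.null(seed)) seed <- model$seed + 500009L
  model$calibration <- calibrate_isotonic(model$oob$pred,
                                          model$y[model$oob$row],
                                          B2 = B2, seed = seed)
  model
}

#' Train, calibrate and evaluate one model per outcome
#'
#' High-level front-end: builds a child-level bootstrap plan, races the
#' candidate algorithms per outcome, calibrates the winner and collects a
#' validation report (per-algorithm raw weighted Brier plus raw/calibrated
#' metrics for the selected model).
#'
#' @param table A filtered `cohort_table`.
#' @param outcomes Outcomes to model (default: all labels of the table).
#' @param algorithms Candidate algorithms.
#' @param B Bootstrap resamples (default 25).
#' @param seed Integer seed.
#' @param grid Hyperparameter grids (default [default_grid]).
#' @param unit Resampling unit, `"child"` (default) or `"record"`.
#' @return List with `models` (named list of calibrated `outcome_model`s)
#'   and `report` (data frame of validation metrics).
#' @export
train_models <- function(table, outcomes = NULL,
                         algorithms = c("random_forest",
                                        "stratified_random_forest",
                                        "elasticnet_logistic"),
                         B = 25, seed = 1, grid = NULL,
                         unit = c("child", "record")) {
  unit <- match.arg(unit)
  cols <- cohort_columns(table)
  if (is.null(outcomes)) outcomes <- cols$labels
  plan <- make_plan(nrow(table), B = B, seed = seed, unit = unit,
                    subjects = if (unit == "child") table$subject_id)
  models <- list()
  report <- list()
  for (oc in outcomes) {
    m <- tune_and_train(table, oc, algorithms, plan, grid = grid, seed = seed)
    m <- calibrate_model(m)
    ev <- evaluate(m)
    models[[oc]] <- m
    row <- data.frame(outcome = oc, algorithm = m$algorithm,
                      raw_weighted_brier = ev$raw$weighted_brier,
                      calibrated_weighted_brier = ev$calibrated$weighted_brier,
                      misclassification = ev$calibrated$misclassification,
                      sensitivity = ev$calibrated$sensitivity,
                      specificity = ev$calibrated$specificity)
    for (alg in algorithms) {
      s <- m$best_per_algorithm
      row[[paste0("wbrier_", alg)]] <-
        s$weighted_brier[s$algorithm == alg]
    }
    report[[oc]] <- row
  }
  list(models = models, report = do.call(rbind, report))
}
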