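# Predictor importance, top-k explanations, partial dependence and the
# per-patient prediction report.

#' Relative variable importance
#'
#' For forests, the total node-impurity decrease attributable to each
#' predictor; for the elastic net, the absolute coefficient magnitude on
#' standardized predictors. Rescaled so the most important predictor scores
#' exactly 100 (invariant to any positive rescaling of the raw
#' importances).
#'
#' @param model An `outcome_model` (or `fitted_candidate`).
#' @return Named numeric vector on a 0-100 scale, decreasing.
#' @export
variable_importance <- function(model) {
  fit <- if (inherits(model, "outcome_model")) model$final_fit else model
  if (!inherits(fit, "fitted_candidate")) stop("model is not fitted")
  if (fit$algorithm == "elasticnet_logistic") {
    beta <- as.numeric(fit$fit$glmnet$beta)
    per_col <- abs(beta) * fit$fit$col_sd
    raw <- tapply(per_col, fit$fit$col_term, sum)
    raw <- stats::setNames(as.numeric(raw), names(raw))
  } else {
    imp <- randomForest::importance(fit$fit)
    raw <- imp[, 1]
    names(raw) <- rownames(imp)
  }
  if (max(raw) <= 0) raw[] <- c(1, rep(0, length(raw) - 1))
  out <- 100 * raw / max(raw)
  sort(out, decreasing = TRUE)
}

#' Top predictors for one patient
#'
#' The up-to-`k` most important predictors with relative importance of at
#' least `min_rel`, together with the patient's measured values. The single
#' most important predictor is always included.
#'
#' @param importance Importance vector from [variable_importance].
#' @param patient_row One-row data frame with predictor values.
#' @param k Maximum predictors to report (default 5).
#' @param min_rel Minimum relative importance on the 0-100 scale
#'   (default 10).
#' @return Data frame with `predictor`, `value`, `importance`, ordered by
#'   importance (descending).
#' @export
top_predictors <- function(importance, patient_row, k = 5, min_rel = 10) {
  keep <- names(importance)[importance >= min_rel]
  if (length(keep) == 0) keep <- names(importance)[1]
  keep <- keep[seq_len(min(k, length(keep)))]
  vals <- vapply(keep, function(nm) {
    if (nm %in% names(patient_row)) {
      as.character(patient_row[[nm]][1])
    } else NA_character_
  }, character(1))
  out <- data.frame(predictor = keep, value = unname(vals),
                    importance = as.numeric(importance[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Partial dependence of an outcome model on one predictor
#'
#' Model probability as a function of one predictor, averaging the
#' prediction over the training rows with that predictor overwritten by
#' each grid value. Probabilities are reported on the raw and the log scale
#' (the display convention for these plots).
#'
#' @param model A calibrated `outcome_model`.
#' @param predictor Predictor name.
#' @param grid Grid of values (default: 30 points over the observed range
#'   for numeric predictors, the observed levels for categorical ones).
#' @param calibrated Use the calibrated probability (default `TRUE`).
#' @return Data frame with `value`, `prob`, `log_prob`.
#' @export
partial_dependence <- function(model, predictor, grid = NULL,
                               calibrated = TRUE) {
  if (!predictor %in% model$predictors) {
    stop("unknown predictor: ", predictor)
  }
  x <- model$x_full
  col <- x[[predictor]]
  if (is.null(grid)) {
    grid <- if (is.numeric(col)) {
      if (length(unique(col)) <= 2) sort(unique(col))
      else seq(min(col), max(col), length.out = 30)
    } else levels(factor(col))
  }
  probs <- vapply(grid, function(v) {
    x2 <- x
    x2[[predictor]] <- if (is.factor(col)) {
      factor(rep(as.character(v), nrow(x2)), levels = levels(col))
    } else rep(as.numeric(v), nrow(x2))
    p <- predict_candidate(model$final_fit, x2)
    if (calibrated && !is.null(model$calibration)) {
      p <- predict(model$calibration, p)
    }
    mean(p)
  }, numeric(1))
  data.frame(value = grid, prob = probs, log_prob = log(pmax(probs, 1e-12)))
}

#' Per-patient prediction report
#'
#' For each outcome model: the calibrated probability that the outcome is
#' present, its complement, and the values of the (up to) five most
#' important predictors. Patient cells that had to be imputed are flagged.
#'
#' @param models Named list of calibrated `outcome_model`s (or the result
#'   of [train_models]).
#' @param patient_record One-row data frame with the cohort's predictor
#'   columns (missing cells allowed).
#' @param k,min_rel See [top_predictors].
#' @return A `prediction_report`: list of per-outcome entries with
#'   `outcome`, `probability`, `complement`, `top_predictors`.
#' @export
render_report <- function(models, patient_record, k = 5, min_rel = 10) {
  if (!is.null(models$models)) models <- models$models
  patient_record <- as.data.frame(patient_record)
  if (nrow(patient_record) != 1) {
    stop("patient_record must be a single row")
  }
  entries <- lapply(models, function(m) {
    missing_cols <- setdiff(m$predictors, names(patient_record))
    if (length(missing_cols) > 0) {
      stop("patient record lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    p <- predict(m, patient_record, calibrated = TRUE)
    imp <- variable_importance(m)
    tp <- top_predictors(imp, patient_record, k = k, min_rel = min_rel)
    tp$imputed <- vapply(tp$predictor, function(nm)
      is.na(patient_record[[nm]][1]), logical(1))
    list(outcome = m$outcome, probability = as.numeric(p),
         complement = 1 - as.numeric(p), top_predictors = tp)
  })
  structure(entries, class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  for (e in x) {
    cat(sprintf("%s: present %.1f%% / absent %.1f%%\n",
                e$outcome, 100 * e$probability, 100 * e$complement))
    tp <- e$top_predictors
    for (i in seq_len(nrow(tp))) {
      cat(sprintf("  %d. %s = %s (importance %.0f%s)\n", i, tp$predictor[i],
                  tp$value[i], tp$importance[i],
                  if (tp$imputed[i]) ", imputed" else ""))
    }
  }
  invisible(x)
}
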