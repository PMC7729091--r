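# Bootstrap training/validation plan, candidate models, weighted-Brier
# tuning and model evaluation. Three candidates are supported: a standard
# random forest, a stratified (balanced) random forest in which every tree
# is grown on a resample with equal counts of both classes, and an
# elastic-net penalized logistic regression.

#' Build an out-of-bag bootstrap plan
#'
#' `B` bootstrap resamples of the records (or of the children, keeping the
#' two sides of a child together, the default used by the training
#' front-end to avoid twin-row leakage). Each in-bag multiset has the size
#' of the dataset; the out-of-bag set is the complement of its support, with
#' expected fraction about 1 - 1/e.
#'
#' @param n_rows Number of records.
#' @param B Number of resamples (default 25).
#' @param seed Integer seed.
#' @param unit `"record"` or `"child"`.
#' @param subjects Child identifier per record (required for
#'   `unit = "child"`).
#' @return A `bootstrap_plan`: list with `B`, `n`, `unit`, `seed`,
#'   `subjects`, `inbag` (list of index multisets) and `oob` (list of index
#'   sets).
#' @export
make_plan <- function(n_rows, B = 25, seed = 1, unit = c("record", "child"),
                      subjects = NULL) {
  unit <- match.arg(unit)
  if (B < 1) stop("B must be at least 1")
  if (n_rows < 1) stop("empty data")
  if (unit == "child" && (is.null(subjects) || length(subjects) != n_rows)) {
    stop("unit = 'child' needs one subject id per record")
  }
  run_seeded(seed, {
    draws <- lapply(seq_len(B), function(b) draw_resample(n_rows, unit, subjects))
    structure(list(B = B, n = n_rows, unit = unit, seed = seed,
                   subjects = subjects,
                   inbag = lapply(draws, `[[`, "inbag"),
                   oob = lapply(draws, `[[`, "oob")),
              class = "bootstrap_plan")
  })
}

draw_resample <- function(n_rows, unit, subjects) {
  if (unit == "record") {
    inbag <- sample.int(n_rows, n_rows, replace = TRUE)
  } else {
    kids <- unique(subjects)
    pick <- sample(kids, length(kids), replace = TRUE)
    rows_of <- split(seq_len(n_rows), subjects)
    inbag <- unlist(rows_of[pick], use.names = FALSE)
  }
  list(inbag = inbag, oob = setdiff(seq_len(n_rows), unique(inbag)))
}

#' Default hyperparameter grids
#'
#' Forests: 500 trees with candidate split-feature counts sqrt(p), p/3 and
#' p/2. Elastic net: mixing parameter alpha in \{0, 0.25, 0.5, 0.75, 1\}
#' crossed with a short penalty-strength ladder.
#'
#' @param p Number of predictors.
#' @param ntree Trees per forest.
#' @return Named list of per-algorithm grid data frames.
#' @export
default_grid <- function(p, ntree = 500) {
  mtry <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), floor(p / 2))))
  forest <- data.frame(mtry = mtry, ntree = ntree)
  list(random_forest = forest,
       stratified_random_forest = forest,
       elasticnet_logistic = expand.grid(alpha = c(0, 0.25, 0.5, 0.75, 1),
                                         lambda = c(0.001, 0.01, 0.1)))
}

# predictors as a model frame with stable factor levels
prepare_frame <- function(table, cols) {
  x <- as.data.frame(table)[cols]
  for (nm in names(x)) {
    if (is.character(x[[nm]])) x[[nm]] <- factor(x[[nm]])
  }
  x
}

#' Fit one candidate model
#'
#' @param algorithm `"random_forest"`, `"stratified_random_forest"` or
#'   `"elasticnet_logistic"`.
#' @param x Data frame of predictors (factors with stable levels).
#' @param y 0/1 outcome vector.
#' @param hyper Named list of hyperparameters (`mtry`/`ntree` for forests;
#'   `alpha`/`lambda` for the elastic net).
#' @param seed Integer seed.
#' @param keep_inbag Record per-tree in-bag counts (forests only; used to
#'   audit the balanced per-tree resamples of the stratified variant).
#' @return A `fitted_candidate` object usable with [predict_candidate].
#' @export
fit_candidate <- function(algorithm, x, y, hyper = list(), seed = 1,
                          keep_inbag = FALSE) {
  if (length(unique(y)) < 2) stop("training rows contain a single class")
  yf <- factor(y, levels = c(0, 1))
  fit <- run_seeded(seed, switch(
    algorithm,
    random_forest = randomForest::randomForest(
      x = x, y = yf, ntree = hyper$ntree %||% 500,
      mtry = hyper$mtry %||% max(1, floor(sqrt(ncol(x)))),
      keep.inbag = keep_inbag),
    stratified_random_forest = {
      m <- min(table(yf))
      randomForest::randomForest(
        x = x, y = yf, ntree = hyper$ntree %||% 500,
        mtry = hyper$mtry %||% max(1, floor(sqrt(ncol(x)))),
        strata = yf, sampsize = c(m, m), replace = TRUE,
        keep.inbag = keep_inbag)
    },
    elasticnet_logistic = {
      mm_full <- stats::model.matrix(~ ., data = x)
      keep <- -1
      mm <- mm_full[, keep, drop = FALSE]
      # map design columns back to their source predictor (factor dummies
      # aggregate onto the factor)
      col_term <- names(x)[attr(mm_full, "assign")[keep]]
      g <- glmnet::glmnet(mm, yf, family = "binomial",
                          alpha = hyper$alpha %||% 0.5,
                          lambda = hyper$lambda %||% 0.01)
      list(glmnet = g, lambda = hyper$lambda %||% 0.01,
           col_sd = apply(mm, 2, stats::sd), col_term = col_term)
    },
    stop("unknown algorithm: ", algorithm)
  ))
  structure(list(algorithm = algorithm, fit = fit, hyper = hyper),
            class = "fitted_candidate")
}

#' Predict class-1 probabilities from a fitted candidate
#'
#' @param object A `fitted_candidate`.
#' @param newx Data frame of predictors (same columns and factor levels as
#'   at fit time).
#' @return Numeric vector of probabilities.
#' @export
predict_candidate <- function(object, newx) {
  if (object$algorithm == "elasticnet_logistic") {
    mm <- stats::model.matrix(~ ., data = newx)[, -1, drop = FALSE]
    as.numeric(stats::predict(object$fit$glmnet, mm, type = "response",
                              s = object$fit$lambda))
  } else {
    stats::predict(object$fit, newx, type = "prob")[, "1"]
  }
}

redraw_until_two_classes <- function(plan, b, y, seed) {
  inbag <- plan$inbag[[b]]
  attempt <- 0
  while (length(unique(y[inbag])) < 2) {
    attempt <- attempt + 1
    if (attempt > 100) {
      stop("could not draw a two-class in-bag resample after 100 attempts")
    }
    inbag <- run_seeded(seed + 7L * b + 101L * attempt,
                        draw_resample(plan$n, plan$unit, plan$subjects))$inbag
  }
  list(inbag = inbag, oob = setdiff(seq_len(plan$n), unique(inbag)))
}

#' Tune and train one outcome model
#'
#' For every algorithm and grid point, fits on each in-bag resample of the
#' plan (median/mode imputation refitted on the in-bag rows each time),
#' predicts the out-of-bag rows, pools the out-of-bag predictions over the
#' `B` resamples and scores them with the weighted Brier score.
#' Hyperparameters minimizing the pooled out-of-bag weighted Brier are
#' selected per algorithm (ties to the earlier grid point); the best
#' algorithm overall supplies the model's pooled predictions, and a final
#' fit on the full (imputed) data supports prediction on new patients.
#' In-bag resamples that miss a class are redrawn (at most 100 attempts).
#'
#' @param table A `cohort_table` (may still contain missing predictor
#'   values; imputation is fitted per resample).
#' @param outcome Label column to model.
#' @param algorithms Candidate algorithms to race.
#' @param plan A `bootstrap_plan` from [make_plan].
#' @param grid Hyperparameter grids, see [default_grid].
#' @param seed Integer seed.
#' @return An `outcome_model` (uncalibrated; see [calibrate_model]).
#' @export
tune_and_train <- function(table, outcome,
                           algorithms = c("random_forest",
                                          "stratified_random_forest",
                                          "elasticnet_logistic"),
                           plan, grid = NULL, seed = 1) {
  cols <- cohort_columns(table)
  if (!outcome %in% cols$labels) {
    stop("outcome '", outcome, "' is not a label of this cohort")
  }
  xcols <- c(cols$predictors, cols$features)
  y <- as.data.frame(table)[[outcome]]
  if (is.null(grid)) grid <- default_grid(length(xcols))
  grid <- grid[algorithms]

  # pooled OOB prediction store: per algorithm, per grid row
  store <- list()
  for (alg in algorithms) {
    store[[alg]] <- lapply(seq_len(nrow(grid[[alg]])), function(i)
      list(row = integer(0), pred = numeric(0), resample = integer(0)))
  }

  for (b in seq_len(plan$B)) {
    rs <- redraw_until_two_classes(plan, b, y, seed)
    if (length(rs$oob) == 0) next
    imp <- impute(table, fit_rows = unique(rs$inbag))
    x <- prepare_frame(imp, xcols)
    for (alg in algorithms) {
      g <- grid[[alg]]
      for (i in seq_len(nrow(g))) {
        fit <- fit_candidate(alg, x[rs$inbag, , drop = FALSE], y[rs$inbag],
                             hyper = as.list(g[i, , drop = FALSE]),
                             seed = seed + 13L * b + i)
        pr <- predict_candidate(fit, x[rs$oob, , drop = FALSE])
        store[[alg]][[i]]$row <- c(store[[alg]][[i]]$row, rs$oob)
        store[[alg]][[i]]$pred <- c(store[[alg]][[i]]$pred, pr)
        store[[alg]][[i]]$resample <- c(store[[alg]][[i]]$resample,
                                        rep(b, length(rs$oob)))
      }
    }
  }

  scores <- do.call(rbind, lapply(algorithms, function(alg) {
    g <- grid[[alg]]
    wb <- vapply(seq_len(nrow(g)), function(i) {
      s <- store[[alg]][[i]]
      weighted_brier(s$pred, y[s$row])
    }, numeric(1))
    hy <- vapply(seq_len(nrow(g)), function(i)
      paste(names(g), unlist(g[i, ]), sep = "=", collapse = ", "),
      character(1))
    data.frame(algorithm = alg, grid_index = seq_len(nrow(g)),
               weighted_brier = wb, hyper = hy, stringsAsFactors = FALSE)
  }))
  best_per_alg <- do.call(rbind, lapply(algorithms, function(alg) {
    s <- scores[scores$algorithm == alg, ]
    s[which.min(s$weighted_brier), ]
  }))
  best <- best_per_alg[which.min(best_per_alg$weighted_brier), ]
  best_alg <- best$algorithm[1]
  best_idx <- best$grid_index[1]
  hyper <- as.list(grid[[best_alg]][best_idx, , drop = FALSE])

  imp_full <- impute(table)
  x_full <- prepare_frame(imp_full, xcols)
  final_fit <- fit_candidate(best_alg, x_full, y, hyper, seed = seed)

  structure(list(outcome = outcome, algorithm = best_alg, hyper = hyper,
                 scores = scores, best_per_algorithm = best_per_alg,
                 oob = store[[best_alg]][[best_idx]], y = y,
                 final_fit = final_fit, x_full = x_full,
                 imputation_values = attr(imp_full, "imputation_values"),
                 predictors = xcols, plan = plan, seed = seed,
                 calibration = NULL),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("<outcome_model> %s: %s, pooled OOB weighted Brier %.3f%s\n",
              x$outcome, x$algorithm,
              min(x$best_per_algorithm$weighted_brier),
              if (is.null(x$calibration)) " (uncalibrated)" else " (calibrated)"))
  invisible(x)
}

#' Predict calibrated outcome probabilities
#'
#' @param object An `outcome_model`.
#' @param newdata Data frame with the model's predictor columns (missing
#'   cells are filled with the model's stored imputation values).
#' @param calibrated Apply the isotonic calibration map (if fitted).
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.outcome_model <- function(object, newdata, calibrated = TRUE, ...) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  nd <- newdata[object$predictors]
  for (nm in object$predictors) {
    miss <- is.na(nd[[nm]])
    if (any(miss)) nd[[nm]][miss] <- object$imputation_values[[nm]]
  }
  for (nm in names(nd)) {
    if (is.character(nd[[nm]]) || is.factor(nd[[nm]])) {
      nd[[nm]] <- factor(as.character(nd[[nm]]),
                         levels = levels(object$x_full[[nm]]))
    }
  }
  p <- predict_candidate(object$final_fit, nd)
  if (calibrated && !is.null(object$calibration)) {
    p <- predict(object$calibration, p)
  }
  p
}

#' Evaluate a model on its pooled out-of-bag predictions
#'
#' Weighted Brier, Brier, misclassification, sensitivity and specificity of
#' the pooled out-of-bag (validation) predictions, before and after
#' isotonic calibration.
#'
#' @param model An `outcome_model`.
#' @param threshold Classification threshold (default 0.5).
#' @return List with components `raw` and (when calibrated) `calibrated`,
#'   each holding the metric values.
#' @export
evaluate <- function(model, threshold = 0.5) {
  p <- model$oob$pred
  o <- model$y[model$oob$row]
  one <- function(pp) {
    c(list(weighted_brier = weighted_brier(pp, o), brier = brier(pp, o)),
      binary_metrics(pp, o, threshold))
  }
  out <- list(raw = one(p))
  if (!is.null(model$calibration)) {
    out$calibrated <- one(predict(model$calibration, p))
  }
  out
}
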