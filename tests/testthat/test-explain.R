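# Importance, top-predictor explanations, partial dependence and reports.

small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cc <- make_clinical_cohort(cohort_spec(n_children = 60, seed = 23),
                                 reference = td_ref)
      tab <- assemble(cc$trials, cc$exams, cc$labels, td_ref, "impairment")
      tab <- filter_outcomes(filter_predictors(tab), min_occurrences = 10)
      plan <- make_plan(nrow(tab), B = 6, seed = 23, unit = "child",
                        subjects = tab$subject_id)
      m <- tune_and_train(tab, "Hamstring spasticity", "random_forest", plan,
                          grid = list(random_forest = data.frame(mtry = 9,
                                                                 ntree = 150)),
                          seed = 23)
      cache <<- list(model = calibrate_model(m), table = tab)
    }
    cache
  }
})

test_that("variable importance is on a 0-100 scale with max exactly 100", {
  m <- small_model()$model
  imp <- variable_importance(m)
  expect_equal(max(imp), 100)
  expect_true(all(imp >= 0))
  expect_setequal(names(imp), m$predictors)
  # rescaling invariance: importance is relative by construction
  expect_equal(unname(imp[1]), 100)
})

test_that("elastic-net importance uses standardized coefficient magnitudes", {
  set.seed(41)
  n <- 300
  x <- data.frame(big = rnorm(n), small = rnorm(n), none = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * x$big + 0.4 * x$small))
  fit <- fit_candidate("elasticnet_logistic", x, y,
                       hyper = list(alpha = 0.5, lambda = 0.01), seed = 1)
  imp <- variable_importance(fit)
  expect_equal(names(imp)[1], "big")
  expect_equal(unname(imp["big"]), 100)
  expect_lt(imp["none"], imp["small"])
})

test_that("top_predictors caps at k and applies the minimum-weight cutoff", {
  imp <- c(a = 100, b = 60, c = 40, d = 30, e = 20, f = 15, g = 5)
  row <- as.data.frame(as.list(seq_along(imp) * 1.0), col.names = names(imp))
  tp <- top_predictors(imp, row, k = 5, min_rel = 10)
  expect_equal(nrow(tp), 5)              # six qualify, capped at five
  expect_identical(tp$predictor, c("a", "b", "c", "d", "e"))
  expect_identical(tp$value[1], "1")
  # one dominant predictor: list of length 1
  imp2 <- c(a = 100, b = 4, c = 2)
  expect_equal(nrow(top_predictors(imp2, row)), 1)
  # everything below the cutoff: the maximum is still reported
  imp3 <- c(a = 100, b = 9)
  tp3 <- top_predictors(imp3, row, min_rel = 200)
  expect_identical(tp3$predictor, "a")
})

test_that("partial dependence is flat for an ignored predictor and matches
           the logistic closed form for an additive model", {
  set.seed(43)
  n <- 400
  x <- data.frame(sig = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * x$sig))
  fit <- fit_candidate("elasticnet_logistic", x, y,
                       hyper = list(alpha = 1, lambda = 0.05), seed = 1)
  model <- structure(list(final_fit = fit, x_full = x,
                          predictors = c("sig", "noise"),
                          calibration = NULL),
                     class = "outcome_model")
  pd <- partial_dependence(model, "sig")
  # oracle: average the logistic closed form over the training rows
  cf <- coef(fit$fit$glmnet)[, 1]
  oracle <- vapply(pd$value, function(v)
    mean(plogis(cf["(Intercept)"] + cf["sig"] * v + cf["noise"] * x$noise)),
    numeric(1))
  expect_equal(pd$prob, oracle, tolerance = 1e-10)
  # monotone and sign-consistent with the single nonzero coefficient
  if (cf["noise"] == 0) {
    expect_true(all(diff(pd$prob) * sign(cf["sig"]) >= 0))
    pd_noise <- partial_dependence(model, "noise")
    expect_lt(diff(range(pd_noise$prob)), 1e-12)
  }
  expect_error(partial_dependence(model, "nope"), "unknown predictor")
})

test_that("binary feature predictors give two-point dependence curves", {
  m <- small_model()$model
  pd <- partial_dependence(m, "Delayed Peak Knee Flexion")
  expect_lte(nrow(pd), 2)
})

test_that("prediction reports are complete, consistent and deterministic", {
  sm <- small_model()
  patient <- as.data.frame(sm$table)[3, , drop = FALSE]
  patient$popliteal_angle <- NA     # force an imputed, flagged cell
  rep1 <- render_report(list(sm$model), patient)
  rep2 <- render_report(list(sm$model), patient)
  expect_identical(rep1, rep2)
  e <- rep1[[1]]
  expect_equal(e$probability + e$complement, 1)
  expect_lte(nrow(e$top_predictors), 5)
  expect_true(all(diff(e$top_predictors$importance) <= 0))
  expect_true(all(e$top_predictors$predictor %in% sm$model$predictors))
  if ("popliteal_angle" %in% e$top_predictors$predictor) {
    expect_true(e$top_predictors$imputed[
      e$top_predictors$predictor == "popliteal_angle"])
  }
  out <- capture.output(print(rep1))
  expect_true(any(grepl("Hamstring spasticity", out)))
  expect_error(render_report(list(sm$model), patient[, 1:4]), "lacks")
})
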