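# Scoring metrics, bootstrap plans, candidate models and calibration.

test_that("brier and weighted_brier match their definitions", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 7), c(1, 1, 0, 0, 0, 1, 0)), 0.25)
  expect_equal(brier(c(1, 0), c(0, 1)), 1)

  # constant-0.5 predictor scores 0.25 weighted or not, any class mix
  for (n1 in c(1, 3, 9)) {
    o <- c(rep(1, n1), rep(0, 10 - n1))
    expect_equal(weighted_brier(rep(0.5, 10), o), 0.25)
    expect_equal(brier(rep(0.5, 10), o), 0.25)
  }
  expect_equal(weighted_brier(c(1, 0, 1), c(1, 0, 1)), 0)
  # hand oracle: w = (1.5, 3, 1.5); (1.5*.04 + 3*.04 + 1.5*.16)/6 = 0.07
  expect_equal(weighted_brier(c(0.8, 0.2, 0.6), c(1, 0, 1)), 0.07)
  expect_error(weighted_brier(c(0.2, 0.3), c(1, 1)), "both classes")
  expect_error(brier(0.5, c(0, 1)), "length")
})

test_that("weighted_brier equals an independent per-element formula", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(4:80, 1)
    o <- rbinom(n, 1, runif(1, 0.15, 0.85))
    if (length(unique(o)) < 2) next
    p <- runif(n)
    w <- ifelse(o == 1, 1 / (sum(o == 1) / n), 1 / (sum(o == 0) / n))
    oracle <- sum(w * (p - o)^2) / sum(w)
    expect_equal(weighted_brier(p, o), oracle, tolerance = 1e-14)
    if (sum(o == 1) * 2 == n) {
      expect_equal(weighted_brier(p, o), brier(p, o), tolerance = 1e-14)
    }
  }
})

test_that("binary_metrics reproduces the confusion-matrix oracle", {
  m <- binary_metrics(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(m$misclassification, 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  perf <- binary_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(unlist(perf), c(misclassification = 0, sensitivity = 1,
                               specificity = 1))
  allpos <- binary_metrics(rep(1, 4), c(1, 0, 1, 0))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_error(binary_metrics(c(0.1, 0.9), c(1, 1)), "undefined")
})

test_that("bootstrap plans are reproducible with disjoint in/out-of-bag sets", {
  p1 <- make_plan(50, B = 5, seed = 3)
  p2 <- make_plan(50, B = 5, seed = 3)
  expect_identical(p1$inbag, p2$inbag)
  for (b in 1:5) {
    expect_length(p1$inbag[[b]], 50)
    expect_length(intersect(p1$oob[[b]], unique(p1$inbag[[b]])), 0)
    expect_setequal(union(p1$oob[[b]], unique(p1$inbag[[b]])), 1:50)
  }
  # expected OOB fraction about 1 - 1/e
  p3 <- make_plan(1000, B = 25, seed = 4)
  frac <- mean(vapply(p3$oob, length, integer(1))) / 1000
  expect_gt(frac, 0.32)
  expect_lt(frac, 0.42)
  expect_error(make_plan(0, B = 5, seed = 1), "empty")
  expect_error(make_plan(10, B = 0, seed = 1), "at least 1")
})

test_that("child-level plans keep both sides of a child together", {
  subj <- rep(sprintf("C%02d", 1:20), each = 2)
  p <- make_plan(40, B = 10, seed = 2, unit = "child", subjects = subj)
  for (b in 1:10) {
    inkids <- unique(subj[p$inbag[[b]]])
    outkids <- unique(subj[p$oob[[b]]])
    expect_length(intersect(inkids, outkids), 0)
  }
  expect_error(make_plan(40, B = 2, seed = 1, unit = "child"), "subject")
})

test_that("the stratified forest balances every per-tree sample", {
  set.seed(8)
  n <- 200
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- c(rep(1, 20), rep(0, 180))          # 90/10 imbalance
  fit <- fit_candidate("stratified_random_forest", x, y,
                       hyper = list(ntree = 50), seed = 1,
                       keep_inbag = TRUE)
  counts <- fit$fit$inbag
  per_tree_pos <- colSums(counts[y == 1, , drop = FALSE])
  per_tree_neg <- colSums(counts[y == 0, , drop = FALSE])
  expect_true(all(per_tree_pos == 20))
  expect_true(all(per_tree_neg == 20))
  expect_error(fit_candidate("random_forest", x, rep(1, n)), "single class")
})

test_that("the elastic net with vanishing penalty approaches the logistic MLE", {
  set.seed(12)
  n <- 400
  x <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.4 + 1.2 * x$x1))
  fit <- fit_candidate("elasticnet_logistic", x, y,
                       hyper = list(alpha = 0, lambda = 1e-5), seed = 1)
  mle <- glm(y ~ x1 + x2, data = cbind(x, y = y), family = binomial)
  p1 <- predict_candidate(fit, x)
  p2 <- unname(predict(mle, x, type = "response"))
  expect_lt(max(abs(p1 - p2)), 0.01)
})

test_that("refits with a fixed seed reproduce predictions exactly", {
  set.seed(31)
  x <- data.frame(a = rnorm(100), b = rnorm(100))
  y <- rbinom(100, 1, plogis(x$a))
  f1 <- fit_candidate("random_forest", x, y, hyper = list(ntree = 60), seed = 9)
  f2 <- fit_candidate("random_forest", x, y, hyper = list(ntree = 60), seed = 9)
  expect_identical(predict_candidate(f1, x), predict_candidate(f2, x))
})

test_that("tuning selects by pooled OOB weighted Brier with tie-break to the
           earlier grid point", {
  cc <- make_clinical_cohort(cohort_spec(n_children = 60, seed = 13),
                             reference = td_ref)
  tab <- assemble(cc$trials, cc$exams, cc$labels, td_ref, "impairment")
  tab <- filter_outcomes(filter_predictors(tab), min_occurrences = 10)
  plan <- make_plan(nrow(tab), B = 6, seed = 13, unit = "child",
                    subjects = tab$subject_id)
  grid <- list(random_forest = data.frame(mtry = c(6, 12), ntree = 100))
  m <- tune_and_train(tab, "Hamstring spasticity", "random_forest", plan,
                      grid = grid, seed = 13)
  expect_s3_class(m, "outcome_model")
  expect_equal(nrow(m$scores), 2)
  best <- m$scores$weighted_brier[m$scores$grid_index ==
                                    m$best_per_algorithm$grid_index[1]]
  expect_equal(min(m$scores$weighted_brier), best)
  # strong-signal cohort beats the null model on pooled OOB predictions
  expect_lt(min(m$scores$weighted_brier), 0.25)
  # one-point grid: selection is trivially that point
  m2 <- tune_and_train(tab, "Hamstring spasticity", "random_forest", plan,
                       grid = list(random_forest = data.frame(mtry = 9,
                                                              ntree = 100)),
                       seed = 13)
  expect_equal(m2$best_per_algorithm$grid_index, 1)
})

test_that("calibration maps are monotone, bounded, and sensible on edge cases", {
  set.seed(17)
  p <- runif(2000)
  o <- rbinom(2000, 1, p)
  map <- calibrate_isotonic(p, o, B2 = 10, seed = 1)
  expect_true(all(diff(map$values) >= 0))
  expect_true(all(map$values >= 0 & map$values <= 1))
  # constant predictions pool to the class rate
  pc <- rep(0.4, 500)
  oc <- rbinom(500, 1, 0.7)
  mc <- calibrate_isotonic(pc, oc, B2 = 10, seed = 2)
  expect_lt(abs(predict(mc, 0.4) - mean(oc)), 0.05)
  expect_error(calibrate_isotonic(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("evaluate reports raw and calibrated pooled-OOB metrics", {
  cc <- make_clinical_cohort(cohort_spec(n_children = 60, seed = 19),
                             reference = td_ref)
  tab <- assemble(cc$trials, cc$exams, cc$labels, td_ref, "impairment")
  tab <- filter_outcomes(filter_predictors(tab), min_occurrences = 10)
  plan <- make_plan(nrow(tab), B = 6, seed = 19, unit = "child",
                    subjects = tab$subject_id)
  m <- tune_and_train(tab, "Hamstring spasticity", "random_forest", plan,
                      grid = list(random_forest = data.frame(mtry = 9,
                                                             ntree = 150)),
                      seed = 19)
  m <- calibrate_model(m)
  ev <- evaluate(m)
  expect_named(ev, c("raw", "calibrated"))
  for (part in ev) {
    expect_true(all(unlist(part) >= 0 & unlist(part) <= 1))
  }
  # the null constant-0.5 predictor scores exactly 0.25 on the same outcomes
  o <- m$y[m$oob$row]
  expect_equal(weighted_brier(rep(0.5, length(o)), o), 0.25)
  # calibration does not materially hurt a well-specified model
  expect_lt(ev$calibrated$weighted_brier, ev$raw$weighted_brier + 0.02)
})
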