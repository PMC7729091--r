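# Cohort assembly, the 90%-of-children predictor filter, the 100-occurrence
# outcome filter, and median/mode imputation.

make_small_cohort <- function(n = 12, seed = 5) {
  sp <- cohort_spec(n_children = n, seed = seed, missing_rate = 0.1)
  make_clinical_cohort(sp, reference = td_ref)
}

test_that("assemble joins features, exams and labels per side", {
  cc <- make_small_cohort()
  tab <- assemble(cc$trials, cc$exams, cc$labels, td_ref, task = "impairment")
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 2 * 12)             # two sides per child
  cols <- cohort_columns(tab)
  expect_setequal(cols$predictors, exam_registry("impairment")$name)
  expect_identical(cols$features, feature_names())
  expect_identical(cols$labels, "Hamstring spasticity")

  # a session without exam rows is dropped, with a message
  exams2 <- cc$exams[cc$exams$session_id != "S0003", ]
  expect_message(
    tab2 <- assemble(cc$trials, exams2, cc$labels, td_ref, "impairment"),
    "2 record")
  expect_equal(nrow(tab2), 22)
})

test_that("the surgery task restricts the predictor registry", {
  cc <- make_small_cohort()
  labels <- cc$labels
  labels[["Femoral derotation osteotomy"]] <- labels[["Hamstring spasticity"]]
  tab <- assemble(cc$trials, cc$exams, labels, td_ref, task = "surgery")
  cols <- cohort_columns(tab)
  expect_setequal(cols$predictors, exam_registry("surgery")$name)
  expect_false(any(startsWith(cols$predictors, "strength_")))
  expect_identical(cols$labels, "Femoral derotation osteotomy")
})

test_that("predictor filter uses the at-least-90%-of-children rule", {
  # exactly 90% of children observed: retained
  x <- rep(1.0, 10); x[1] <- NA
  tab <- toy_cohort(10, x)
  kept <- filter_predictors(tab, threshold = 0.90)
  expect_true("pred" %in% cohort_columns(kept)$predictors)

  # 899 of 1000 children observed (89.9%): dropped
  x2 <- rep(1.0, 1000); x2[1:101] <- NA
  tab2 <- toy_cohort(1000, x2)
  kept2 <- filter_predictors(tab2, threshold = 0.90)
  expect_false("pred" %in% cohort_columns(kept2)$predictors)
  expect_identical(attr(kept2, "dropped_predictors"), "pred")

  # fully observed: retained
  kept3 <- filter_predictors(toy_cohort(10, rep(2, 10)))
  expect_true("pred" %in% cohort_columns(kept3)$predictors)

  # completeness is per child: value on one side only still counts
  tab4 <- toy_cohort(10, rep(1, 10))
  tab4$pred[seq(2, 20, by = 2)] <- NA    # right side missing everywhere
  expect_true("pred" %in%
                cohort_columns(filter_predictors(tab4))$predictors)
})

test_that("outcome filter keeps labels with at least min_occurrences positives", {
  lab100 <- c(rep(1, 100), rep(0, 100))
  lab99 <- c(rep(1, 99), rep(0, 101))
  tab <- toy_cohort(100, rnorm(100),
                    labels = list(often = lab100, rare = lab99))
  out <- filter_outcomes(tab, min_occurrences = 100)
  expect_identical(cohort_columns(out)$labels, "often")
  expect_identical(attr(out, "dropped_labels"), "rare")
  # all labels frequent enough: identity
  out2 <- filter_outcomes(tab, min_occurrences = 50)
  expect_setequal(cohort_columns(out2)$labels, c("often", "rare"))
})

test_that("imputation uses medians, modes and lexicographic tie-breaks", {
  tab <- toy_cohort(2, c(1, 2))
  tab$pred <- c(1, 2, 3, NA)
  imp <- impute(tab)
  expect_equal(imp$pred[4], 2)          # median of {1,2,3}
  expect_true(attr(imp, "imputed")[4, "pred"])
  expect_false(any(attr(imp, "imputed")[1:3, "pred"]))

  tab$pred <- c(1, 2, 3, 4)
  tab$pred[2] <- NA
  imp2 <- impute(tab, fit_rows = c(1, 3, 4))
  expect_equal(imp2$pred[2], 3)         # median of {1,3,4}

  # even count: midpoint convention
  tabe <- toy_cohort(3, c(0, 0, 0))
  tabe$pred <- c(1, 2, 3, 4, NA, NA)
  expect_equal(impute(tabe)$pred[5], 2.5)

  # categorical: mode, ties broken lexicographically
  tabc <- toy_cohort(2, c(1, 1))
  tabc$pred <- c("a", "a", "b", NA)
  expect_identical(impute(tabc)$pred[4], "a")
  tabc$pred <- c("b", "a", NA, NA)
  expect_identical(impute(tabc)$pred[3], "a")

  tabn <- toy_cohort(2, c(1, 1))
  tabn$pred <- c(NA, NA, NA, NA_real_)
  expect_error(impute(tabn), "no observed value")
})

test_that("imputation fitted on training rows never reads validation rows", {
  tab <- toy_cohort(10, rnorm(10))
  tab$pred[3] <- NA
  fit_rows <- 1:10
  a <- impute(tab, fit_rows = fit_rows)
  tab2 <- tab
  tab2$pred[11:20] <- tab2$pred[11:20] + 1000   # perturb held-out rows only
  tab2$pred[3] <- NA
  b <- impute(tab2, fit_rows = fit_rows)
  expect_identical(a$pred[3], b$pred[3])
})

test_that("filters commute for disjoint predictor and label columns", {
  x <- rep(1.0, 50); x[1:10] <- NA
  lab <- c(rep(1, 30), rep(0, 70))
  tab <- toy_cohort(50, x, labels = list(y = lab))
  ab <- filter_outcomes(filter_predictors(tab, 0.9), 40)
  ba <- filter_predictors(filter_outcomes(tab, 40), 0.9)
  expect_identical(cohort_columns(ab), cohort_columns(ba))
  expect_identical(as.data.frame(ab), as.data.frame(ba))
})
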