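# Shared fixtures: a 30-subject typically-developing cohort and its
# reference set, reused across test files.

td_trials <- make_reference_cohort(30, seed = 1)
td_ref <- build_reference(td_trials)

win_idx_test <- function(a, b) (a:b) + 1L

# a minimal trial whose every curve is constant `value`
constant_trial <- function(value, id = "T1", sides = "left",
                           group = "typically_developing") {
  combos <- curve_combinations()
  curves <- list()
  for (side in sides) {
    curves <- c(curves, lapply(seq_len(nrow(combos)), function(i) {
      gait_curve(combos$joint[i], combos$plane[i], side, rep(value, 101))
    }))
  }
  gait_trial(id, id, curves,
             foot_off = stats::setNames(rep(60, length(sides)), sides),
             group = group)
}

# small cohort table built directly (for filter/impute boundary tests)
toy_cohort <- function(n_children, predictor, labels = NULL) {
  tab <- data.frame(
    subject_id = rep(sprintf("C%04d", seq_len(n_children)), each = 2),
    session_id = rep(sprintf("S%04d", seq_len(n_children)), each = 2),
    side = rep(c("left", "right"), n_children),
    stringsAsFactors = FALSE
  )
  tab$pred <- rep(predictor, each = 2)
  lab_cols <- character(0)
  if (!is.null(labels)) {
    for (nm in names(labels)) tab[[nm]] <- labels[[nm]]
    lab_cols <- names(labels)
  }
  gaitdss:::cohort_attr(tab, predictors = "pred", features = character(0),
                        labels = lab_cols)
}
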