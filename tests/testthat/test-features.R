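# Curve primitives and the 49-feature detector registry.

test_that("rom, window_mean, value_at and slope match closed forms", {
  ramp <- (0:100) / 10
  expect_equal(rom(rep(4, 101)), 0)
  expect_equal(rom(ramp), 10)
  expect_equal(rom(ramp, win(20, 45)), 2.5)

  expect_equal(window_mean(rep(3, 101)), 3)
  expect_equal(window_mean(ramp), 5)
  expect_equal(window_mean(ramp, win(20, 45)), 3.25)

  expect_equal(value_at(ramp, 0), 0)
  expect_equal(value_at(ramp, 45), 4.5)
  expect_error(value_at(ramp, 101), "0..100")

  expect_equal(slope(ramp, 0:100), 0.1)
  expect_equal(slope(rep(2, 101), 0:100), 0)
  lin <- 2 - 0.3 * (0:100)
  expect_equal(slope(lin, win(20, 45)), -0.3)
  # least-squares oracle on a noisy window
  set.seed(4)
  v <- rnorm(101)
  w <- win(10, 40)
  oracle <- unname(coef(lm(v[w + 1] ~ w))[2])
  expect_equal(slope(v, w), oracle)
  expect_error(slope(v, 10), "length >= 2")
  expect_error(rom(v, integer(0)), "empty window")
})

test_that("extremum finds prominent peaks/pits and rejects degenerate cases", {
  t <- 0:100
  hump <- exp(-((t - 30) / 10)^2)
  ex <- extremum(hump, 0:100, "peak")
  expect_equal(ex$t, 30)
  expect_equal(ex$value, 1)
  # dense-evaluation oracle: the sample max is the same point
  expect_equal(ex$t, which.max(hump) - 1L)

  expect_null(extremum(t / 10, 0:100, "peak"))   # monotone: no interior max
  expect_null(extremum(rep(1, 101), 0:100, "peak"))
  pit <- extremum(-hump, 0:100, "pit")
  expect_equal(pit$t, 30)
  expect_equal(pit$value, -1)

  # low-prominence wiggles are not peaks
  wig <- t / 10 + 0.05 * sin(t)
  expect_null(extremum(wig, 0:100, "peak"))
  # window restriction
  two <- exp(-((t - 30) / 8)^2) + 0.8 * exp(-((t - 70) / 8)^2)
  expect_equal(extremum(two, 0:100, "peak")$t, 30)
  expect_equal(extremum(two, 50:100, "peak")$t, 70)
})

test_that("bump_count identifies the double-bump period", {
  t <- 0:100
  expect_equal(bump_count(cos(4 * pi * (t - 12) / 100)), 2L)
  expect_equal(bump_count(cos(2 * pi * (t - 25) / 100)), 1L)
  expect_equal(bump_count(rep(2, 101)), 0L)
})

test_that("template_correlation takes the best match and handles zero variance", {
  t <- 0:100
  a <- sin(2 * pi * t / 100)
  b <- cos(2 * pi * t / 100)
  expect_equal(template_correlation(a, list(a)), 1)
  expect_equal(template_correlation(-a, list(a)), -1)
  expect_equal(template_correlation(a, list(-a, a)), 1)   # max over bank
  expect_equal(template_correlation(rep(1, 101), list(a)), 0)
  expect_equal(template_correlation(a, list(rep(2, 101))), 0)
  expect_error(template_correlation(a, list()), "empty template")
  expect_gt(template_correlation(a, list(b, a * 3 + 5)), 0.99)
})

test_that("lr_difference sums signed and absolute side differences", {
  tr <- td_trials[[1]]
  same <- tr
  same$curves[["hip_sagittal_left"]] <-
    gait_curve("hip", "sagittal", "left",
               same$curves[["hip_sagittal_right"]]$values)
  expect_equal(lr_difference(same, "hip", "sagittal", "signed_mean_diff"), 0)
  shifted <- tr
  shifted$curves[["hip_sagittal_left"]] <-
    gait_curve("hip", "sagittal", "left",
               shifted$curves[["hip_sagittal_right"]]$values + 5)
  expect_equal(lr_difference(shifted, "hip", "sagittal", "signed_mean_diff"), 5)
  expect_equal(lr_difference(shifted, "hip", "sagittal", "mean_abs_diff"), 5)
  # alternating +/-1 difference: direct-summation oracle
  alt <- rep(c(1, -1), length.out = 101)
  alt_tr <- tr
  alt_tr$curves[["knee_sagittal_left"]] <-
    gait_curve("knee", "sagittal", "left",
               alt_tr$curves[["knee_sagittal_right"]]$values + alt)
  expect_equal(lr_difference(alt_tr, "knee", "sagittal", "signed_mean_diff"),
               mean(alt))
  expect_equal(lr_difference(alt_tr, "knee", "sagittal", "mean_abs_diff"), 1)
  one_sided <- constant_trial(1)
  expect_error(lr_difference(one_sided, "hip", "sagittal"), "both sides")
})

test_that("the registry holds exactly 49 features with the documented tally", {
  reg <- feature_registry(include_custom = FALSE)
  expect_length(reg, 49)
  tally <- table(vapply(reg, `[[`, character(1), "structure"),
                 vapply(reg, `[[`, character(1), "plane"))
  expect_equal(tally["pelvis", "sagittal"][[1]], 6)
  expect_equal(tally["pelvis", "coronal"][[1]], 2)
  expect_equal(tally["pelvis", "transverse"][[1]], 3)
  expect_equal(tally["hip", "sagittal"][[1]], 6)
  expect_equal(tally["hip", "coronal"][[1]], 4)
  expect_equal(tally["hip", "transverse"][[1]], 3)
  expect_equal(tally["knee", "sagittal"][[1]], 10)
  expect_equal(tally["ankle", "sagittal"][[1]], 11)
  expect_equal(tally["ankle", "transverse"][[1]], 1)
  expect_equal(tally["foot_progression", "transverse"][[1]], 3)
})

test_that("detect_feature applies strict band semantics", {
  # hand-built reference of constant curves 25/30/35 (both sides): the
  # [20,45] hip mean band has mean 30 and sample SD of {25,25,30,30,35,35}
  ref_trials <- lapply(c(25, 30, 35), function(v)
    constant_trial(v, id = paste0("R", v), sides = c("left", "right")))
  ref <- build_reference(ref_trials)
  band <- ref$bands[["hip_sagittal_mean_20_45"]]
  expect_equal(band$mean, 30)
  expect_equal(band$sd, sd(c(25, 25, 30, 30, 35, 35)))
  # patient mean well below mean - 1 SD: present
  expect_true(detect_feature("Increased Hip Extension at Mid Stance",
                             constant_trial(20, group = "patient"), "left", ref))
  # statistic equal to the band mean: absent
  expect_false(detect_feature("Increased Hip Extension at Mid Stance",
                              constant_trial(30, group = "patient"), "left", ref))
  # boundary equality (exactly mean - 1 SD) counts as absent
  expect_false(detect_feature(
    "Increased Hip Extension at Mid Stance",
    constant_trial(band$mean - band$sd, group = "patient"), "left", ref))
})

test_that("No 1st Rocker fires exactly when the angle rises off initial contact", {
  tr <- td_trials[[1]]
  expect_false(detect_feature("No 1st Rocker", tr, "left", td_ref))
  v <- tr$curves[["ankle_sagittal_left"]]$values
  v[2] <- v[1] + 0.2
  tr$curves[["ankle_sagittal_left"]] <- gait_curve("ankle", "sagittal", "left", v)
  expect_true(detect_feature("No 1st Rocker", tr, "left", td_ref))
})

test_that("threshold features respond monotonically to shifts toward the band", {
  # Foot Drop: statistic < mean - 1 SD; shifting the curve upward (toward
  # the band mean) can only switch present -> absent, never the reverse
  tr <- implant_feature(td_trials[[4]], "Foot Drop", td_ref)
  states <- vapply(seq(0, 12, by = 0.5), function(d) {
    tr2 <- tr
    v <- tr2$curves[["ankle_sagittal_left"]]$values + d
    tr2$curves[["ankle_sagittal_left"]] <-
      gait_curve("ankle", "sagittal", "left", v)
    detect_feature("Foot Drop", tr2, "left", td_ref)
  }, logical(1))
  expect_true(states[1])
  expect_false(any(diff(!states) < 0))  # once absent, stays absent
})

test_that("compound features imply their components", {
  compounds <- list(
    c("Decreased Pelvic Tilt + Increased ROM", "Decreased Pelvic Tilt"),
    c("Increased Pelvic Tilt + Increased ROM", "Increased Pelvic Tilt"),
    c("Increased Hip Flexion + Decreased ROM", "Increased Hip Flexion"),
    c("Delayed + Decreased Peak Knee Flexion", "Delayed Peak Knee Flexion"),
    c("Delayed + Increased Peak Knee Flexion", "Delayed Peak Knee Flexion"),
    c("Increased Flexion at Initial Contact + Early Knee Extension",
      "Increased Flexion at Initial Contact")
  )
  for (pair in compounds) {
    tr <- implant_feature(td_trials[[6]], pair[1], td_ref)
    expect_true(detect_feature(pair[1], tr, "left", td_ref), label = pair[1])
    expect_true(detect_feature(pair[2], tr, "left", td_ref),
                label = paste(pair[1], "implies", pair[2]))
  }
})

test_that("extraction is deterministic and covers both sides", {
  fv1 <- extract_features(td_trials[[5]], td_ref)
  fv2 <- extract_features(td_trials[[5]], td_ref)
  expect_identical(fv1, fv2)
  expect_identical(fv1$side, c("left", "right"))
  expect_identical(names(fv1)[-1], feature_names())
})

test_that("custom detectors behave like built-ins", {
  on.exit(remove_custom_detector("Foot Drop (redeclared)"), add = TRUE)
  make_custom_detector(
    "Foot Drop (redeclared)", "ankle", "sagittal",
    conditions = list(list(type = "band", stat = "ankle_sagittal_mean_80_100",
                           dir = "<", k = 1)),
    reference = td_ref)
  # equivalence on typical, implanted and perturbed trials
  cases <- c(td_trials[1:5],
             list(implant_feature(td_trials[[2]], "Foot Drop", td_ref),
                  implant_feature(td_trials[[3]], "Dorsiflexion in Swing",
                                  td_ref)))
  set.seed(9)
  for (i in seq_len(20)) {
    tr <- cases[[1 + (i %% length(cases))]]
    v <- tr$curves[["ankle_sagittal_left"]]$values + rnorm(1, 0, 4)
    tr$curves[["ankle_sagittal_left"]] <-
      gait_curve("ankle", "sagittal", "left", v)
    expect_identical(
      detect_feature("Foot Drop", tr, "left", td_ref),
      detect_feature("Foot Drop (redeclared)", tr, "left", td_ref))
  }
  # validation errors
  expect_error(make_custom_detector("x", "hip", "sagittal", list()),
               "empty predicate")
  expect_error(make_custom_detector("Foot Drop", "ankle", "sagittal",
                                    list(list(type = "expr", fn = identity))),
               "shadows")
  expect_error(make_custom_detector("y", "hip", "sagittal",
                                    list(list(type = "band", stat = "nope",
                                              dir = "<", k = 1))),
               "unknown band statistic")
})

test_that("a custom band detector fires exactly when its oracle condition holds", {
  on.exit(remove_custom_detector("crouchy knee"), add = TRUE)
  make_custom_detector(
    "crouchy knee", "knee", "sagittal",
    conditions = list(list(type = "band", stat = "knee_sagittal_mean_20_45",
                           dir = ">", k = 2)))
  band <- td_ref$bands[["knee_sagittal_mean_20_45"]]
  for (delta in c(0, 4, 8, 12)) {
    tr <- td_trials[[7]]
    v <- tr$curves[["knee_sagittal_left"]]$values
    v[win_idx_test(20, 45)] <- v[win_idx_test(20, 45)] + delta
    tr$curves[["knee_sagittal_left"]] <-
      gait_curve("knee", "sagittal", "left", v)
    stat <- window_mean(tr$curves[["knee_sagittal_left"]]$values, win(20, 45))
    expect_identical(detect_feature("crouchy knee", tr, "left", td_ref),
                     stat > band$mean + 2 * band$sd)
  }
})
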