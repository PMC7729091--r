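# Synthetic data: typically-developing reference cohorts, feature
# implantation, and clinical cohorts with known logistic structure.
#
# Typical curves follow smooth base shapes resembling normal pediatric gait.
# Subject variation uses an antithetic balanced design: each subject carries
# a sign z = +/-1 (balanced across the cohort; the right side uses -z) that
# scales a shared offset-plus-amplitude perturbation,
#   curve(t) = (1 + eps b) base(t) + eps o,   eps = side_sign * z.
# Every location/scale detector statistic then deviates from the cohort mean
# by exactly one magnitude, strictly inside one sample SD of its own
# reference band, so all 49 features are guaranteed absent on every
# unperturbed typical trial while the bands keep realistic nonzero spread.

run_seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

#' The synthetic curve template model
#'
#' Base shapes (degrees, over t = 0..100) for each joint/plane, with the
#' subject-level offset magnitude `offset` (degrees) and relative amplitude
#' magnitude `amp` applied through the antithetic balanced design.
#'
#' @return Named list (by `joint_plane`) of lists with `base` (numeric 101),
#'   `offset` and `amp`.
#' @export
curve_model <- function() {
  t <- 0:100
  shapes <- list(
    pelvis_sagittal = list(base = 12 + 1.5 * sin(2 * pi * t / 100),
                           offset = 1.5, amp = 0.10),
    pelvis_coronal = list(base = 2.5 * sin(2 * pi * t / 100),
                          offset = 1.0, amp = 0.10),
    pelvis_transverse = list(base = 4 * sin(2 * pi * t / 100),
                             offset = 2.0, amp = 0.10),
    hip_sagittal = list(base = 10 + 20 * cos(2 * pi * (t + 10) / 100),
                        offset = 3.0, amp = 0.06),
    hip_coronal = list(base = 2 + 3 * sin(2 * pi * t / 100),
                       offset = 1.5, amp = 0.08),
    hip_transverse = list(base = 5 + 2 * sin(2 * pi * t / 100),
                          offset = 3.0, amp = 0.08),
    knee_sagittal = list(base = 5 + 15 * exp(-((t - 15) / 10)^2) +
                           55 * exp(-((t - 70) / 11)^2),
                         offset = 2.5, amp = 0.06),
    knee_coronal = list(base = 2 + 1.5 * sin(2 * pi * t / 100),
                        offset = 1.0, amp = 0.08),
    knee_transverse = list(base = 5 + 2 * sin(2 * pi * t / 100),
                           offset = 2.0, amp = 0.08),
    ankle_sagittal = list(base = -6 * exp(-((t - 8) / 6)^2) +
                            12 * exp(-((t - 42) / 18)^2) -
                            18 * exp(-((t - 63) / 7)^2) +
                            2 * exp(-((t - 85) / 12)^2),
                          offset = 1.5, amp = 0.08),
    ankle_transverse = list(base = 8 + 2 * sin(2 * pi * t / 100),
                            offset = 2.5, amp = 0.08),
    foot_progression_transverse = list(base = -8 + 1.5 * sin(2 * pi * t / 100),
                                       offset = 2.5, amp = 0.08)
  )
  shapes
}

synth_trial <- function(trial_id, subject_id, z, group, model = curve_model(),
                        foot_off = 60) {
  curves <- list()
  for (key in names(model)) {
    parts <- parse_curve_column(paste0(key, "_left"))
    m <- model[[key]]
    for (s in c("left", "right")) {
      eps <- if (s == "left") z else -z
      vals <- (1 + eps * m$amp) * m$base + eps * m$offset
      curves[[length(curves) + 1L]] <-
        gait_curve(parts$joint, parts$plane, s, vals)
    }
  }
  gait_trial(trial_id, subject_id, curves,
             foot_off = c(left = foot_off, right = foot_off), group = group)
}

#' Generate a typically-developing reference cohort
#'
#' `n` trials (one per subject, both sides) from [curve_model] under the
#' antithetic balanced design; deterministic for a given seed. With odd `n`
#' one subject receives the neutral sign 0; even `n` gives the exact
#' balance that guarantees the detector-absence margin.
#'
#' @param n Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param model A [curve_model] list.
#' @return List of [gait_trial] objects.
#' @export
make_reference_cohort <- function(n, seed = 1, model = curve_model()) {
  if (n < 2) stop("a reference cohort needs at least 2 subjects")
  run_seeded(seed, {
    z <- rep(c(1, -1), n %/% 2)
    if (n %% 2 == 1) z <- c(z, 0)
    z <- sample(z)
    lapply(seq_len(n), function(i) {
      synth_trial(sprintf("TD%03d", i), sprintf("TD%03d", i), z[i],
                  "typically_developing", model)
    })
  })
}

# ---------------------------------------------------------------------------
# Feature implantation
# ---------------------------------------------------------------------------

# weight vector over t = 0..100: 1 on [a, b], raised-cosine ramps of length
# `ramp` fading to 0 outside (clipped at the cycle ends)
window_weights <- function(a, b, ramp = 6) {
  t <- 0:100
  w <- numeric(101)
  w[t >= a & t <= b] <- 1
  if (ramp > 0) {
    for (k in seq_len(ramp)) {
      tl <- a - k
      if (tl >= 0) w[tl + 1] <- max(w[tl + 1], 0.5 * (1 + cos(pi * k / (ramp + 1))))
      tr <- b + k
      if (tr <= 100) w[tr + 1] <- max(w[tr + 1], 0.5 * (1 + cos(pi * k / (ramp + 1))))
    }
  }
  w
}

shift_window_vals <- function(v, a, b, delta, ramp = 6) {
  v + delta * window_weights(a, b, ramp)
}

scale_about_mean <- function(v, factor) mean(v) + factor * (v - mean(v))

set_trial_curve <- function(trial, joint, plane, side, vals) {
  trial$curves[[curve_key(joint, plane, side)]] <-
    gait_curve(joint, plane, side, vals)
  trial
}

# margin beyond the k SD threshold used by implants
implant_margin <- function(band) max(0.5 * band$sd, 0.5)
target_above <- function(band, k) band$mean + k * band$sd + implant_margin(band)
target_below <- function(band, k) band$mean - k * band$sd - implant_margin(band)

#' Implant one kinematic feature into a trial
#'
#' Returns a modified copy of the trial in which the named feature's
#' predicate holds with a safety margin beyond its detection threshold
#' (at least half a band SD), touching only the curves the feature reads.
#' Statistics of unrelated joints are left unchanged; related detectors on
#' the same curve may legitimately co-fire.
#'
#' @param trial A [gait_trial] (typically a synthetic typical trial).
#' @param feature_name One of [feature_names].
#' @param reference A `reference_set` supplying the bands and templates.
#' @param side Side to implant on (default `"left"`).
#' @return The modified [gait_trial].
#' @export
implant_feature <- function(trial, feature_name, reference, side = "left") {
  if (!feature_name %in% feature_names()) {
    stop("unknown feature: ", feature_name)
  }
  b <- function(nm) get_band(reference, nm)
  stat <- function(nm, s = side) eval_stat(b(nm)$spec, trial, s)
  cv <- function(joint, plane, s = side) {
    get_curve(trial, joint, plane, s)$values
  }
  set_cv <- function(joint, plane, vals, s = side) {
    set_trial_curve(trial, joint, plane, s, vals)
  }
  tt <- 0:100

  trial <- switch(
    feature_name,
    "Increased ROM (double bump)" = {
      rb <- b("pelvis_sagittal_rom_full")
      mb <- b("pelvis_sagittal_mean_full")
      tmpl <- get_templates(reference, "double_bump")[[2]]  # peaks at t=12, 62
      amp <- (target_above(rb, 2) + 1) / (max(tmpl) - min(tmpl))
      vals <- mb$mean + amp * tmpl
      tr <- set_trial_curve(trial, "pelvis", "sagittal", "left", vals)
      set_trial_curve(tr, "pelvis", "sagittal", "right", vals)
    },
    "Decreased Pelvic Tilt" = {
      mb <- b("pelvis_sagittal_mean_full")
      set_cv("pelvis", "sagittal",
             cv("pelvis", "sagittal") + target_below(mb, 1) -
               stat("pelvis_sagittal_mean_full"))
    },
    "Decreased Pelvic Tilt + Increased ROM" = {
      mb <- b("pelvis_sagittal_mean_full")
      rb <- b("pelvis_sagittal_rom_full")
      v <- scale_about_mean(cv("pelvis", "sagittal"),
                            target_above(rb, 2) / stat("pelvis_sagittal_rom_full"))
      set_cv("pelvis", "sagittal", v + target_below(mb, 1) - mean(v))
    },
    "Increased Pelvic Tilt" = {
      mb <- b("pelvis_sagittal_mean_full")
      set_cv("pelvis", "sagittal",
             cv("pelvis", "sagittal") + target_above(mb, 1) -
               stat("pelvis_sagittal_mean_full"))
    },
    "Increased Pelvic Tilt + Increased ROM" = {
      mb <- b("pelvis_sagittal_mean_full")
      rb <- b("pelvis_sagittal_rom_full")
      v <- scale_about_mean(cv("pelvis", "sagittal"),
                            target_above(rb, 2) / stat("pelvis_sagittal_rom_full"))
      set_cv("pelvis", "sagittal", v + target_above(mb, 1) - mean(v))
    },
    "Unilateral Bump" = {
      rb <- b("pelvis_sagittal_rom_full")
      set_cv("pelvis", "sagittal",
             scale_about_mean(cv("pelvis", "sagittal"),
                              target_above(rb, 2) / stat("pelvis_sagittal_rom_full")))
    },
    "Increased Pelvic ROM" = {
      rb <- b("pelvis_coronal_rom_full")
      set_cv("pelvis", "coronal",
             scale_about_mean(cv("pelvis", "coronal"),
                              target_above(rb, 2) / stat("pelvis_coronal_rom_full")))
    },
    "Pelvic Elevation/Depression" = {
      db <- b("pelvis_coronal_lrdiff")
      cur <- lr_difference(trial, "pelvis", "coronal", "signed_mean_diff")
      set_cv("pelvis", "coronal",
             cv("pelvis", "coronal", "left") + target_above(db, 1) - cur,
             s = "left")
    },
    "Increased Pelvic Rotation ROM" = {
      rb <- b("pelvis_transverse_rom_full")
      set_cv("pelvis", "transverse",
             scale_about_mean(cv("pelvis", "transverse"),
                              target_above(rb, 2) / stat("pelvis_transverse_rom_full")))
    },
    "Pelvic Pro/Retraction" = {
      db <- b("pelvis_transverse_lrdiff")
      cur <- lr_difference(trial, "pelvis", "transverse", "signed_mean_diff")
      set_cv("pelvis", "transverse",
             cv("pelvis", "transverse", "left") + target_above(db, 1) - cur,
             s = "left")
    },
    "Reversed ROM" = {
      v <- cv("pelvis", "transverse")
      set_cv("pelvis", "transverse", 2 * mean(v) - v)
    },
    "Decreased Hip Flexion at Initial Contact" = {
      vb <- b("hip_sagittal_value_0")
      delta <- target_below(vb, 2) - stat("hip_sagittal_value_0")
      set_cv("hip", "sagittal",
             shift_window_vals(cv("hip", "sagittal"), 0, 0, delta, ramp = 10))
    },
    "Hip Extension Deficit" = {
      sb <- b("hip_sagittal_mean_stance")
      rb <- b("hip_sagittal_rom_full")
      v <- scale_about_mean(cv("hip", "sagittal"),
                            max(0.1, target_below(rb, 2)) /
                              stat("hip_sagittal_rom_full"))
      sw <- stance_swing_windows(trial, side)$stance
      set_cv("hip", "sagittal", v + target_above(sb, 1) - window_mean(v, sw))
    },
    "Hip Hyper-Flexion" = {
      pb <- b("hip_sagittal_peak_swing")
      delta <- target_above(pb, 2) - stat("hip_sagittal_peak_swing")
      set_cv("hip", "sagittal",
             shift_window_vals(cv("hip", "sagittal"), 84, 96, delta, ramp = 8))
    },
    "Increased Hip Extension at Mid Stance" = {
      mb <- b("hip_sagittal_mean_20_45")
      delta <- target_below(mb, 1) - stat("hip_sagittal_mean_20_45")
      set_cv("hip", "sagittal",
             shift_window_vals(cv("hip", "sagittal"), 20, 45, delta, ramp = 6))
    },
    "Increased Hip Flexion" = {
      sb <- b("hip_sagittal_mean_stance")
      v <- cv("hip", "sagittal")
      sw <- stance_swing_windows(trial, side)$stance
      delta <- max(target_above(sb, 1) - window_mean(v, sw), -min(v) + 1)
      set_cv("hip", "sagittal", v + delta)
    },
    "Increased Hip Flexion + Decreased ROM" = {
      sb <- b("hip_sagittal_mean_stance")
      rb <- b("hip_sagittal_rom_full")
      v <- scale_about_mean(cv("hip", "sagittal"),
                            max(0.1, target_below(rb, 2)) /
                              stat("hip_sagittal_rom_full"))
      sw <- stance_swing_windows(trial, side)$stance
      delta <- max(target_above(sb, 1) - window_mean(v, sw), -min(v) + 1)
      set_cv("hip", "sagittal", v + delta)
    },
    "Excessive Hip Abduction" = {
      st <- b("hip_coronal_mean_stance")
      sw <- b("hip_coronal_mean_swing")
      delta <- min(target_below(st, 1) - stat("hip_coronal_mean_stance"),
                   target_below(sw, 1) - stat("hip_coronal_mean_swing"))
      set_cv("hip", "coronal", cv("hip", "coronal") + delta)
    },
    "Excessive Hip Abduction in Swing" = {
      sw <- b("hip_coronal_mean_swing")
      delta <- target_below(sw, 1) - stat("hip_coronal_mean_swing")
      set_cv("hip", "coronal",
             shift_window_vals(cv("hip", "coronal"), 61, 100, delta, ramp = 5))
    },
    "Excessive Hip Adduction" = {
      st <- b("hip_coronal_mean_stance")
      sw <- b("hip_coronal_mean_swing")
      delta <- max(target_above(st, 1) - stat("hip_coronal_mean_stance"),
                   target_above(sw, 1) - stat("hip_coronal_mean_swing"))
      set_cv("hip", "coronal", cv("hip", "coronal") + delta)
    },
    "Hip Adduction in Stance" = {
      st <- b("hip_coronal_mean_stance")
      delta <- target_above(st, 1) - stat("hip_coronal_mean_stance")
      set_cv("hip", "coronal",
             shift_window_vals(cv("hip", "coronal"), 0, 60, delta, ramp = 5))
    },
    "Hip External Rotation" = {
      mb <- b("hip_transverse_mean_full")
      delta <- target_below(mb, 1) - stat("hip_transverse_mean_full")
      set_cv("hip", "transverse", cv("hip", "transverse") + delta)
    },
    "Hip Internal Rotation" = {
      mb <- b("hip_transverse_mean_full")
      delta <- target_above(mb, 1) - stat("hip_transverse_mean_full")
      set_cv("hip", "transverse", cv("hip", "transverse") + delta)
    },
    "Increased Hip Internal Rotation at Late Stance" = {
      lb <- b("hip_transverse_mean_40_60")
      shape <- exp(-((tt - 50) / 30)^2)
      base_level <- b("hip_transverse_mean_full")$mean - 2
      amp <- (target_above(lb, 1) - base_level) /
        mean(shape[win_idx(win(40, 60))])
      set_cv("hip", "transverse", base_level + amp * shape)
    },
    "Reduced Flexion at Loading" = {
      mb <- b("knee_sagittal_mean_0_20")
      delta <- target_below(mb, 1) - stat("knee_sagittal_mean_0_20")
      set_cv("knee", "sagittal",
             shift_window_vals(cv("knee", "sagittal"), 0, 20, delta, ramp = 6))
    },
    "Decreased Peak Knee Flexion" = {
      pb <- b("knee_sagittal_peak_swing")
      delta <- target_below(pb, 2) - stat("knee_sagittal_peak_swing")
      set_cv("knee", "sagittal",
             shift_window_vals(cv("knee", "sagittal"), 61, 100, delta, ramp = 4))
    },
    "Delayed + Decreased Peak Knee Flexion" = {
      pb <- b("knee_sagittal_peak_swing")
      v <- cv("knee", "sagittal")
      V <- target_below(pb, 2)
      v <- shift_window_vals(v, 61, 100, V - 3 - stat("knee_sagittal_peak_swing"),
                             ramp = 4)
      flat <- v[win_idx(win(88, 92))]
      v <- shift_window_vals(v, 88, 92, V - max(flat), ramp = 4)
      set_cv("knee", "sagittal", v)
    },
    "Delayed + Increased Peak Knee Flexion" = {
      pb <- b("knee_sagittal_peak_swing")
      v <- cv("knee", "sagittal")
      V <- target_above(pb, 2)
      flat <- v[win_idx(win(88, 92))]
      set_cv("knee", "sagittal",
             shift_window_vals(v, 88, 92, V - max(flat), ramp = 4))
    },
    "Delayed Peak Knee Flexion" = {
      v <- cv("knee", "sagittal")
      sw <- stance_swing_windows(trial, side)$swing
      V <- max(v[win_idx(sw)]) + 2
      flat <- v[win_idx(win(88, 92))]
      set_cv("knee", "sagittal",
             shift_window_vals(v, 88, 92, V - max(flat), ramp = 4))
    },
    "Knee Flexion in Mid Stance" = {
      mb <- b("knee_sagittal_mean_20_45")
      delta <- target_above(mb, 1) - stat("knee_sagittal_mean_20_45")
      set_cv("knee", "sagittal",
             shift_window_vals(cv("knee", "sagittal"), 20, 45, delta, ramp = 5))
    },
    "Knee Hyperextension" = {
      mb <- b("knee_sagittal_mean_20_45")
      delta <- target_below(mb, 1) - stat("knee_sagittal_mean_20_45")
      set_cv("knee", "sagittal",
             shift_window_vals(cv("knee", "sagittal"), 20, 45, delta, ramp = 5))
    },
    "Increased Flexion at Initial Contact" = {
      vb <- b("knee_sagittal_value_0")
      delta <- target_above(vb, 2) - stat("knee_sagittal_value_0")
      set_cv("knee", "sagittal",
             shift_window_vals(cv("knee", "sagittal"), 0, 6, delta, ramp = 8))
    },
    "Increased Flexion at Initial Contact + Early Knee Extension" = {
      vb <- b("knee_sagittal_value_0")
      nb <- b("knee_sagittal_min_10_25")
      v <- cv("knee", "sagittal")
      v <- shift_window_vals(v, 0, 6, target_above(vb, 2) - v[1], ramp = 6)
      pit_target <- min(nb$mean - 0.5 * nb$sd - 0.5, v[1] - 12)
      v <- shift_window_vals(v, 14, 22, pit_target - min(v[win_idx(win(14, 22))]),
                             ramp = 4)
      set_cv("knee", "sagittal", v)
    },
    "Increased Peak Knee Flexion" = {
      pb <- b("knee_sagittal_peak_swing")
      delta <- target_above(pb, 2) - stat("knee_sagittal_peak_swing")
      set_cv("knee", "sagittal",
             shift_window_vals(cv("knee", "sagittal"), 66, 74, delta, ramp = 5))
    },
    "Reduced Dorsiflexion" = {
      mb <- b("ankle_sagittal_mean_0_50")
      delta <- target_below(mb, 1) - stat("ankle_sagittal_mean_0_50")
      set_cv("ankle", "sagittal",
             shift_window_vals(cv("ankle", "sagittal"), 0, 50, delta, ramp = 6))
    },
    "Descending 2nd Rocker" = {
      v <- cv("ankle", "sagittal")
      v20 <- v[win_idx(20)[1]]
      v45 <- v[win_idx(45)[1]]
      d45 <- min(-2, v20 - 6.5) - v45
      delta <- numeric(101)
      sel <- tt >= 20 & tt <= 45
      delta[sel] <- d45 * (tt[sel] - 20) / 25
      sel2 <- tt > 45 & tt <= 52
      delta[sel2] <- d45 * (1 - (tt[sel2] - 45) / 7)
      set_cv("ankle", "sagittal", v + delta)
    },
    "Dorsiflexion in Swing" = {
      sb <- b("ankle_sagittal_mean_swing")
      delta <- target_above(sb, 1) - stat("ankle_sagittal_mean_swing")
      set_cv("ankle", "sagittal",
             shift_window_vals(cv("ankle", "sagittal"), 61, 100, delta, ramp = 5))
    },
    "Foot Drop" = {
      fb <- b("ankle_sagittal_mean_80_100")
      delta <- target_below(fb, 1) - stat("ankle_sagittal_mean_80_100")
      set_cv("ankle", "sagittal",
             shift_window_vals(cv("ankle", "sagittal"), 80, 100, delta, ramp = 6))
    },
    "Horizontal 2nd Rocker" = {
      v <- cv("ankle", "sagittal")
      target <- -1 - 0.02 * (tt - 32.5)
      w <- window_weights(20, 45, ramp = 5)
      set_cv("ankle", "sagittal", (1 - w) * v + w * target)
    },
    "Increased Dorsiflexion" = {
      mb <- b("ankle_sagittal_mean_20_45")
      delta <- target_above(mb, 1) - stat("ankle_sagittal_mean_20_45")
      set_cv("ankle", "sagittal",
             shift_window_vals(cv("ankle", "sagittal"), 20, 45, delta, ramp = 5))
    },
    "Increased Max. Dorsiflexion" = {
      xb <- b("ankle_sagittal_max_stance")
      delta <- target_above(xb, 2) - stat("ankle_sagittal_max_stance")
      set_cv("ankle", "sagittal",
             shift_window_vals(cv("ankle", "sagittal"), 38, 46, delta, ramp = 5))
    },
    "Increased Plantarflexion" = {
      mb <- b("ankle_sagittal_mean_20_45")
      delta <- target_below(mb, 1) - stat("ankle_sagittal_mean_20_45")
      set_cv("ankle", "sagittal",
             shift_window_vals(cv("ankle", "sagittal"), 20, 45, delta, ramp = 5))
    },
    "Insufficient Pre-positioning" = {
      vb <- b("ankle_sagittal_value_100")
      delta <- target_above(vb, 2) - stat("ankle_sagittal_value_100")
      set_cv("ankle", "sagittal",
             shift_window_vals(cv("ankle", "sagittal"), 92, 100, delta, ramp = 6))
    },
    "No 1st Rocker" = {
      v <- cv("ankle", "sagittal")
      d <- v[1] - v[2] + 0.7
      delta <- numeric(101)
      delta[2:5] <- d * c(1, 0.6, 0.3, 0.1)
      set_cv("ankle", "sagittal", v + delta)
    },
    "Short 2nd Rocker" = {
      tmpl <- get_templates(reference, "short_2nd_rocker")[[1]]
      set_cv("ankle", "sagittal", tmpl)
    },
    "Ankle Internal Rotation" = {
      sb <- b("ankle_transverse_mean_stance")
      delta <- target_above(sb, 1) - stat("ankle_transverse_mean_stance")
      set_cv("ankle", "transverse", cv("ankle", "transverse") + delta)
    },
    "External Foot Progression (Wave) in Swing only" = {
      v <- cv("foot_progression", "transverse")
      wave <- ifelse(tt > 60,
                     -8 * sin(pi * (tt - 60) / 20) * sin(pi * (tt - 60) / 40), 0)
      set_cv("foot_progression", "transverse", v + wave)
    },
    "In-toe" = {
      sb <- b("foot_progression_transverse_mean_stance")
      delta <- target_above(sb, 1) - stat("foot_progression_transverse_mean_stance")
      set_cv("foot_progression", "transverse",
             cv("foot_progression", "transverse") + delta)
    },
    "Out-toe" = {
      sb <- b("foot_progression_transverse_mean_stance")
      delta <- target_below(sb, 1) - stat("foot_progression_transverse_mean_stance")
      set_cv("foot_progression", "transverse",
             cv("foot_progression", "transverse") + delta)
    },
    stop("no implant recipe for feature: ", feature_name)
  )
  trial
}

# ---------------------------------------------------------------------------
# Clinical cohort generation
# ---------------------------------------------------------------------------

exam_generators <- function() {
  list(
    age = list(mean = 10, sd = 2.4, lo = 3, hi = 20),
    height = list(mean = 134, sd = 16, lo = 80, hi = 190),
    weight = list(mean = 31, sd = 10, lo = 10, hi = 90),
    true_popliteal_angle = list(mean = 40, sd = 12, lo = 0, hi = 90),
    popliteal_angle = list(mean = 45, sd = 12, lo = 10, hi = 90),
    dynamic_popliteal_angle = list(mean = 55, sd = 12, lo = 15, hi = 95),
    dorsiflexion_knee_flexed = list(mean = 15, sd = 8, lo = -20, hi = 40),
    dorsiflexion_knee_extended = list(mean = 8, sd = 8, lo = -25, hi = 30),
    dynamic_dorsiflexion = list(mean = 0, sd = 10, lo = -30, hi = 25),
    hip_abduction_knee_extended = list(mean = 35, sd = 8, lo = 5, hi = 60),
    hip_extension = list(mean = 5, sd = 6, lo = -20, hi = 25),
    duncan_ely_slow = list(mean = 45, sd = 15, lo = 0, hi = 100),
    duncan_ely_fast = list(mean = 40, sd = 15, lo = 0, hi = 100),
    hip_internal_rotation = list(mean = 55, sd = 12, lo = 10, hi = 90),
    hip_external_rotation = list(mean = 35, sd = 10, lo = 0, hi = 70),
    femoral_anteversion = list(mean = 30, sd = 10, lo = 0, hi = 60),
    tibial_torsion = list(mean = 15, sd = 8, lo = -15, hi = 45),
    thigh_heel_angle = list(mean = 12, sd = 8, lo = -15, hi = 40),
    selective_motor_control_ankle = list(levels = c("0", "1", "2"),
                                         probs = c(0.2, 0.5, 0.3)),
    foot_posture_midfoot = list(levels = c("cavus", "neutral", "planus"),
                                probs = c(0.15, 0.6, 0.25)),
    foot_posture_forefoot = list(levels = c("abductus", "adductus", "neutral"),
                                 probs = c(0.15, 0.2, 0.65)),
    foot_posture_hindfoot_sagittal = list(levels = c("calcaneus", "equinus",
                                                     "neutral"),
                                          probs = c(0.1, 0.3, 0.6)),
    foot_posture_hindfoot_coronal = list(levels = c("neutral", "valgus",
                                                    "varus"),
                                         probs = c(0.5, 0.3, 0.2))
  )
}

gen_exam_column <- function(name, n) {
  g <- exam_generators()[[name]]
  if (startsWith(name, "strength_")) {
    return(sample(as.character(0:5), n, replace = TRUE,
                  prob = c(0.02, 0.06, 0.12, 0.25, 0.35, 0.20)))
  }
  if (is.null(g)) stop("no generator for exam column ", name)
  if (!is.null(g$levels)) {
    sample(g$levels, n, replace = TRUE, prob = g$probs)
  } else {
    pmin(g$hi, pmax(g$lo, stats::rnorm(n, g$mean, g$sd)))
  }
}

#' Specification for a synthetic clinical cohort
#'
#' @param n_children Number of children (two sides each).
#' @param task `"impairment"` or `"surgery"`.
#' @param outcomes Outcome names (subset of [outcome_registry]).
#' @param prevalence Target prevalence per outcome (recycled).
#' @param active Named list: per outcome, a named numeric vector of
#'   per-standard-deviation log-odds for the active continuous predictors.
#'   The default uses three strong predictors (odds ratios of about 3.5
#'   per SD).
#' @param linked_features Named list: per outcome, one kinematic feature
#'   implanted with probability `p_implant_pos` when the label is positive
#'   and `p_implant_neg` otherwise.
#' @param p_implant_pos,p_implant_neg Implant probabilities.
#' @param missing_rate Completely-at-random missingness rate applied to the
#'   non-anthropometric examination columns.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_children = 500, task = "impairment",
                        outcomes = "Hamstring spasticity",
                        prevalence = 0.3,
                        active = NULL,
                        linked_features = NULL,
                        p_implant_pos = 0.7, p_implant_neg = 0.05,
                        missing_rate = 0.05, seed = 1) {
  if (is.null(active)) {
    active <- stats::setNames(rep(list(c(
      popliteal_angle = log(3.5),
      dorsiflexion_knee_extended = -log(3.5),
      hip_internal_rotation = log(3.5)
    )), length(outcomes)), outcomes)
  }
  if (is.null(linked_features)) {
    linked_features <- stats::setNames(
      rep(list("Delayed Peak Knee Flexion"), length(outcomes)), outcomes)
  }
  prevalence <- rep_len(prevalence, length(outcomes))
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("prevalence must lie in (0, 1)")
  }
  structure(list(n_children = n_children, task = task, outcomes = outcomes,
                 prevalence = prevalence, active = active,
                 linked_features = linked_features,
                 p_implant_pos = p_implant_pos, p_implant_neg = p_implant_neg,
                 missing_rate = missing_rate, seed = seed),
            class = "cohort_spec")
}

solve_intercept <- function(lp, prev) {
  f <- function(a) mean(stats::plogis(a + lp)) - prev
  if (f(-30) > 0 || f(30) < 0) stop("unreachable prevalence")
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic clinical cohort with known structure
#'
#' Children with two sides each: examination predictors drawn from plausible
#' clinical ranges, binary outcomes drawn from a logistic model on the
#' standardized active predictors (intercept solved to hit the target
#' prevalence), linked kinematic features implanted with outcome-dependent
#' probability, and completely-at-random missingness on the examination
#' columns. The full generating truth is returned for recovery tests.
#'
#' @param spec A [cohort_spec].
#' @param reference Optional `reference_set` used for implantation
#'   (defaults to an internally generated 30-subject reference cohort).
#' @return List with `trials`, `exams`, `labels`, `reference`, and `truth`
#'   (intercepts, coefficients, implant draws, seed).
#' @export
make_clinical_cohort <- function(spec = cohort_spec(), reference = NULL) {
  if (is.null(reference)) {
    reference <- build_reference(make_reference_cohort(30, spec$seed + 7919))
  }
  gens <- exam_generators()
  reg <- exam_registry(spec$task)
  run_seeded(spec$seed, {
    n <- spec$n_children
    ids <- sprintf("P%04d", seq_len(n))
    rows <- data.frame(
      subject_id = rep(ids, each = 2),
      session_id = rep(sprintf("S%04d", seq_len(n)), each = 2),
      side = rep(c("left", "right"), n),
      stringsAsFactors = FALSE
    )
    nr <- nrow(rows)
    exams <- rows
    for (i in seq_len(nrow(reg))) {
      nm <- reg$name[i]
      if (reg$side_specific[i]) {
        exams[[nm]] <- gen_exam_column(nm, nr)
      } else {
        per_child <- gen_exam_column(nm, n)
        exams[[nm]] <- rep(per_child, each = 2)
      }
    }
    # height/weight depend on age for realism
    if (all(c("age", "height", "weight") %in% names(exams))) {
      age_child <- exams$age[seq(1, nr, by = 2)]
      h <- pmax(70, 82 + 5.2 * age_child + stats::rnorm(n, 0, 6))
      w <- pmax(10, -12 + 3.2 * age_child + stats::rnorm(n, 0, 5))
      exams$height <- rep(h, each = 2)
      exams$weight <- rep(w, each = 2)
    }

    labels <- rows[c("session_id", "side")]
    truth <- list(seed = spec$seed, intercepts = numeric(0),
                  coefficients = spec$active, linked = spec$linked_features,
                  implanted = list())
    for (k in seq_along(spec$outcomes)) {
      oc <- spec$outcomes[k]
      beta <- spec$active[[oc]]
      lp <- numeric(nr)
      for (p in names(beta)) {
        g <- gens[[p]]
        lp <- lp + beta[[p]] * (exams[[p]] - g$mean) / g$sd
      }
      a <- solve_intercept(lp, spec$prevalence[k])
      truth$intercepts[oc] <- a
      labels[[oc]] <- stats::rbinom(nr, 1, stats::plogis(a + lp))
    }

    # patient trials: continuous perturbations, then outcome-linked implants
    zl <- pmax(-2, pmin(2, stats::rnorm(n, 0, 0.8)))
    trials <- lapply(seq_len(n), function(i) {
      synth_trial(sprintf("S%04d", i), ids[i], zl[i], "patient")
    })
    for (k in seq_along(spec$outcomes)) {
      oc <- spec$outcomes[k]
      lf <- spec$linked_features[[oc]]
      if (is.null(lf)) next
      pr <- ifelse(labels[[oc]] == 1, spec$p_implant_pos, spec$p_implant_neg)
      do_implant <- stats::rbinom(nr, 1, pr) == 1
      truth$implanted[[oc]] <- do_implant
      for (r in which(do_implant)) {
        child <- (r + 1) %/% 2
        s <- rows$side[r]
        trials[[child]] <- implant_feature(trials[[child]], lf, reference,
                                           side = s)
      }
    }

    # completely-at-random missingness on non-anthropometric exam columns
    miss_cols <- reg$name[reg$category != "anthropometric"]
    for (nm in miss_cols) {
      hit <- stats::runif(nr) < spec$missing_rate
      exams[[nm]][hit] <- NA
    }
    list(trials = trials, exams = exams, labels = labels,
         reference = reference, truth = truth)
  })
}
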