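# Reference ("typical") statistic bands and template banks, built from
# typically-developing trials. Every band follows the same four-step
# procedure: compute a statistic on each individual reference curve, then
# take the mean and sample SD over all reference curves; a patient curve is
# then compared with mean +/- k SD.

#' Statistic specifications backing the detector registry
#'
#' Each specification names a deterministic, side-symmetric statistic of one
#' joint/plane curve (or of a left-right pair), together with its window.
#'
#' @return A named list of statistic specifications (lists with `name`,
#'   `joint`, `plane`, `stat`, and window parameters).
#' @export
stat_registry <- function() {
  spec <- function(name, joint, plane, stat, window = "full", t = NULL) {
    list(name = name, joint = joint, plane = plane, stat = stat,
         window = window, t = t)
  }
  specs <- list(
    spec("pelvis_sagittal_mean_full", "pelvis", "sagittal", "mean"),
    spec("pelvis_sagittal_rom_full", "pelvis", "sagittal", "rom"),
    spec("pelvis_coronal_rom_full", "pelvis", "coronal", "rom"),
    spec("pelvis_coronal_lrdiff", "pelvis", "coronal", "lr_diff"),
    spec("pelvis_transverse_rom_full", "pelvis", "transverse", "rom"),
    spec("pelvis_transverse_lrdiff", "pelvis", "transverse", "lr_diff"),
    spec("hip_sagittal_value_0", "hip", "sagittal", "value_at", t = 0),
    spec("hip_sagittal_mean_stance", "hip", "sagittal", "mean", "stance"),
    spec("hip_sagittal_rom_full", "hip", "sagittal", "rom"),
    spec("hip_sagittal_peak_swing", "hip", "sagittal", "peak", "swing"),
    spec("hip_sagittal_mean_20_45", "hip", "sagittal", "mean", c(20, 45)),
    spec("hip_coronal_mean_stance", "hip", "coronal", "mean", "stance"),
    spec("hip_coronal_mean_swing", "hip", "coronal", "mean", "swing"),
    spec("hip_transverse_mean_full", "hip", "transverse", "mean"),
    spec("hip_transverse_mean_40_60", "hip", "transverse", "mean", c(40, 60)),
    spec("knee_sagittal_mean_0_20", "knee", "sagittal", "mean", c(0, 20)),
    spec("knee_sagittal_peak_swing", "knee", "sagittal", "peak", "swing"),
    spec("knee_sagittal_mean_20_45", "knee", "sagittal", "mean", c(20, 45)),
    spec("knee_sagittal_value_0", "knee", "sagittal", "value_at", t = 0),
    spec("knee_sagittal_min_10_25", "knee", "sagittal", "min", c(10, 25)),
    spec("ankle_sagittal_mean_0_50", "ankle", "sagittal", "mean", c(0, 50)),
    spec("ankle_sagittal_mean_swing", "ankle", "sagittal", "mean", "swing"),
    spec("ankle_sagittal_mean_80_100", "ankle", "sagittal", "mean", c(80, 100)),
    spec("ankle_sagittal_mean_20_45", "ankle", "sagittal", "mean", c(20, 45)),
    spec("ankle_sagittal_max_stance", "ankle", "sagittal", "max", "stance"),
    spec("ankle_sagittal_value_100", "ankle", "sagittal", "value_at", t = 100),
    spec("ankle_transverse_mean_stance", "ankle", "transverse", "mean", "stance"),
    spec("foot_progression_transverse_rom_swing", "foot_progression",
         "transverse", "rom", "swing"),
    spec("foot_progression_transverse_mean_stance", "foot_progression",
         "transverse", "mean", "stance")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

resolve_window <- function(window, trial, side) {
  if (is.character(window)) {
    switch(window,
           full = 0:100,
           stance = stance_swing_windows(trial, side)$stance,
           swing = stance_swing_windows(trial, side)$swing,
           stop("unknown window tag: ", window))
  } else {
    win(window[1], window[2])
  }
}

#' Evaluate a statistic specification on one trial side
#'
#' @param spec An entry of [stat_registry()] (or a spec built the same way).
#' @param trial A [gait_trial].
#' @param side `"left"` or `"right"` (ignored for left-right difference
#'   statistics).
#' @return The statistic value in degrees.
#' @export
eval_stat <- function(spec, trial, side) {
  if (spec$stat == "lr_diff") {
    return(lr_difference(trial, spec$joint, spec$plane, "signed_mean_diff"))
  }
  cv <- get_curve(trial, spec$joint, spec$plane, side)
  w <- resolve_window(spec$window, trial, side)
  switch(spec$stat,
         mean = window_mean(cv, w),
         rom = rom(cv, w),
         value_at = value_at(cv, spec$t),
         peak = window_peak(cv, w)$value,
         min = min(cv$values[win_idx(w)]),
         max = max(cv$values[win_idx(w)]),
         stop("unknown statistic: ", spec$stat))
}

#' Compute one reference band
#'
#' Evaluates the statistic on each individual reference curve (both sides of
#' every typically-developing trial are pooled; left-right difference
#' statistics contribute one value per trial) and returns the mean and
#' sample SD (n-1 denominator).
#'
#' @param trials List of [gait_trial] objects.
#' @param spec A statistic specification (see [stat_registry]).
#' @return An object of class `stat_band`: list with `spec`, `mean`, `sd`,
#'   `n_ref`.
#' @export
compute_band <- function(trials, spec) {
  vals <- numeric(0)
  for (tr in trials) {
    if (spec$stat == "lr_diff") {
      if (all(c("left", "right") %in% trial_sides(tr))) {
        vals <- c(vals, eval_stat(spec, tr, "left"))
      }
    } else {
      for (s in trial_sides(tr)) {
        ok <- !is.null(tr$curves[[curve_key(spec$joint, spec$plane, s)]])
        if (ok) vals <- c(vals, eval_stat(spec, tr, s))
      }
    }
  }
  if (length(vals) < 2) {
    stop("insufficient reference curves for statistic '", spec$name, "'")
  }
  structure(list(spec = spec, mean = mean(vals), sd = stats::sd(vals),
                 n_ref = length(vals)),
            class = "stat_band")
}

#' @export
print.stat_band <- function(x, ...) {
  cat(sprintf("<stat_band> %s: mean %.3f, sd %.3f (n = %d)\n",
              x$spec$name, x$mean, x$sd, x$n_ref))
  invisible(x)
}

# mean curve (pooled over sides and trials) for one joint/plane
mean_reference_curve <- function(trials, joint, plane) {
  acc <- matrix(NA_real_, nrow = 0, ncol = 101)
  for (tr in trials) {
    for (s in trial_sides(tr)) {
      cv <- tr$curves[[curve_key(joint, plane, s)]]
      if (!is.null(cv)) acc <- rbind(acc, cv$values)
    }
  }
  if (nrow(acc) == 0) stop("no reference curves for ", joint, "/", plane)
  colMeans(acc)
}

#' Default template bank
#'
#' Template curves for the correlation-based detectors. The double-bump
#' templates are two-cycle cosines at several phases; the reversed-rotation
#' template is the sign-flipped typical transverse pelvis mean curve; the
#' short second-rocker template is an analytic ankle shape with an early
#' dorsiflexion peak, declining mid-stance dorsiflexion and a push-off
#' plantarflexion valley; the external foot-progression wave template is the
#' typical mean curve plus an external wave confined to swing. All are
#' overridable via `build_reference(..., templates = )`.
#'
#' @param trials Reference trials used for the data-driven templates.
#' @return Named list of template banks (each a list of 101-sample vectors).
#' @export
default_templates <- function(trials) {
  t <- 0:100
  double_bump <- lapply(c(0, 6.25, 12.5), function(ph) {
    cos(4 * pi * (t - 12.5 - ph) / 100)
  })
  pelvis_rot_mean <- mean_reference_curve(trials, "pelvis", "transverse")
  reversed_rom <- list(mean(pelvis_rot_mean) - (pelvis_rot_mean - mean(pelvis_rot_mean)))
  short_2nd_rocker <- list(
    10 * exp(-((t - 12) / 9)^2) - 3 - 15 * exp(-((t - 62) / 8)^2) +
      4 * exp(-((t - 90) / 10)^2)
  )
  fp_mean <- mean_reference_curve(trials, "foot_progression", "transverse")
  wave <- ifelse(t > 60, -8 * sin(pi * (t - 60) / 20) * sin(pi * (t - 60) / 40),
                 0)
  external_fp_wave <- list(fp_mean + wave)
  list(double_bump = double_bump, reversed_rom = reversed_rom,
       short_2nd_rocker = short_2nd_rocker,
       external_fp_wave = external_fp_wave)
}

#' Build a reference set from typically-developing trials
#'
#' Computes every statistic band in [stat_registry] and attaches the
#' template bank. By default only the first trial per subject enters the
#' normative set.
#'
#' @param trials List of [gait_trial] objects (typically developing).
#' @param templates Optional named list overriding [default_templates].
#' @param one_per_subject Keep only the first trial of each subject.
#' @return An object of class `reference_set` with elements `bands`
#'   (named list of `stat_band`), `templates`, and `n_trials`.
#' @export
build_reference <- function(trials, templates = NULL, one_per_subject = TRUE) {
  if (length(trials) < 2) stop("need at least 2 typically-developing trials")
  if (one_per_subject) {
    subj <- vapply(trials, `[[`, character(1), "subject_id")
    trials <- trials[!duplicated(subj)]
  }
  bands <- lapply(stat_registry(), function(sp) compute_band(trials, sp))
  if (is.null(templates)) templates <- default_templates(trials)
  structure(list(bands = bands, templates = templates,
                 n_trials = length(trials)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d bands, %d template banks (n = %d trials)\n",
              length(x$bands), length(x$templates), x$n_trials))
  invisible(x)
}

get_band <- function(reference, name) {
  b <- reference$bands[[name]]
  if (is.null(b)) stop("reference set has no band '", name, "'")
  b
}

get_templates <- function(reference, name) {
  tp <- reference$templates[[name]]
  if (is.null(tp) || length(tp) == 0) {
    stop("reference set has no template bank '", name, "'")
  }
  tp
}

#' Serialize / load a reference set
#'
#' The band table is written as a tab-separated text file and each template
#' as a two-column curve table, inside `dir`.
#'
#' @param reference A `reference_set`.
#' @param dir Directory (created if needed).
#' @return `write_reference` returns `dir` invisibly; `read_reference`
#'   returns a `reference_set`.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bands <- do.call(rbind, lapply(reference$bands, function(b) {
    data.frame(name = b$spec$name, mean = b$mean, sd = b$sd, n = b$n_ref)
  }))
  utils::write.table(format(bands, digits = 12), file.path(dir, "bands.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tdir <- file.path(dir, "templates")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(reference$templates)) {
    bank <- reference$templates[[nm]]
    for (i in seq_along(bank)) {
      tab <- data.frame(t = 0:100, value = sprintf("%.6f", bank[[i]]))
      utils::write.table(tab, file.path(tdir, sprintf("%s_%02d.tsv", nm, i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "bands.tsv"),
                           stringsAsFactors = FALSE)
  registry <- stat_registry()
  bands <- list()
  for (i in seq_len(nrow(tab))) {
    nm <- trimws(tab$name[i])
    sp <- registry[[nm]]
    if (is.null(sp)) stop("unknown band in file: ", nm)
    bands[[nm]] <- structure(list(spec = sp, mean = as.numeric(tab$mean[i]),
                                  sd = as.numeric(tab$sd[i]),
                                  n_ref = as.integer(tab$n[i])),
                             class = "stat_band")
  }
  tfiles <- list.files(file.path(dir, "templates"), full.names = TRUE)
  templates <- list()
  for (f in tfiles) {
    nm <- sub("_[0-9]+\\.tsv$", "", basename(f))
    v <- utils::read.delim(f)$value
    templates[[nm]] <- c(templates[[nm]], list(as.numeric(v)))
  }
  structure(list(bands = bands, templates = templates,
                 n_trials = max(vapply(bands, `[[`, integer(1), "n_ref")) %/% 2L),
            class = "reference_set")
}
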