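# Plain-text serialization of gait trials, examination tables and labels.
#
# Curve file format: UTF-8, '#'-prefixed "key: value" header lines
# (trial_id, subject_id, group, foot_off_left, foot_off_right), then a
# tab-separated table with a `t` column and one `<joint>_<plane>_<side>`
# column per curve. Angles written with 4 decimal places.

parse_curve_column <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) < 3) stop("malformed curve column name: ", name)
  n <- length(parts)
  list(joint = paste(parts[seq_len(n - 2)], collapse = "_"),
       plane = parts[n - 1], side = parts[n])
}

#' Read a gait trial from a curve file
#'
#' Curves whose row count differs from 101 are resampled onto the gait-cycle
#' grid with [resample_to_cycle].
#'
#' @param path Path to a curve file written by [write_trial] (or following
#'   the same format).
#' @return A validated [gait_trial].
#' @export
read_trial <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[trimws(key)]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  cols <- setdiff(names(tab), "t")
  for (cl in cols) {
    if (!is.numeric(tab[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[cl]]))))[1]
      stop("non-numeric value in column '", cl, "', row ", bad)
    }
  }
  curves <- lapply(cols, function(cl) {
    sel <- parse_curve_column(cl)
    vals <- tab[[cl]]
    if (length(vals) != 101L) vals <- resample_to_cycle(vals)
    gait_curve(sel$joint, sel$plane, sel$side, vals)
  })
  foot_off <- c()
  if (!is.null(meta$foot_off_left)) {
    foot_off["left"] <- as.numeric(meta$foot_off_left)
  }
  if (!is.null(meta$foot_off_right)) {
    foot_off["right"] <- as.numeric(meta$foot_off_right)
  }
  gait_trial(trial_id = meta$trial_id %||% basename(path),
             subject_id = meta$subject_id %||% "unknown",
             curves = curves, foot_off = foot_off,
             group = meta$group %||% "patient")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a gait trial to a curve file
#'
#' @param trial A [gait_trial].
#' @param path Output path.
#' @param digits Decimal places for angles (at least 4).
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, digits = 4) {
  digits <- max(4L, as.integer(digits))
  hdr <- c(
    paste0("# trial_id: ", trial$trial_id),
    paste0("# subject_id: ", trial$subject_id),
    paste0("# group: ", trial$group)
  )
  for (s in names(trial$foot_off)) {
    hdr <- c(hdr, sprintf("# foot_off_%s: %s", s,
                          format(trial$foot_off[[s]], digits = 10)))
  }
  tab <- data.frame(t = 0:100)
  for (key in names(trial$curves)) {
    tab[[key]] <- sprintf(paste0("%.", digits, "f"),
                          trial$curves[[key]]$values)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(tab), sep = "\t")), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Examination predictor registry
# ---------------------------------------------------------------------------

#' Registry of physical-examination predictors
#'
#' The fixed column registry of physical-examination measurements used as
#' predictors. The impairment task uses the full set (anthropometric,
#' strength grades, range-of-motion/spasticity measures, bone alignment);
#' the surgery task uses the reduced set that survives missing-data
#' constraints in routine surgical work-ups (no strength grades, fewer
#' range-of-motion measures, tibial torsion only).
#'
#' @param task `"impairment"` or `"surgery"`.
#' @return Data frame with columns `name`, `category`, `type`
#'   (`"continuous"` or `"categorical"`), and `side_specific`.
#' @export
exam_registry <- function(task = c("impairment", "surgery")) {
  task <- match.arg(task)
  reg <- rbind(
    data.frame(name = c("age", "height", "weight"),
               category = "anthropometric", type = "continuous",
               side_specific = FALSE, stringsAsFactors = FALSE),
    data.frame(name = c("strength_knee_extensors", "strength_quadriceps_lag",
                        "strength_abdominals", "strength_knee_flexors",
                        "strength_hip_extensors", "strength_hip_abductors",
                        "strength_dorsiflexors", "strength_plantarflexors",
                        "strength_invertors", "strength_hip_flexors"),
               category = "strength", type = "categorical",
               side_specific = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                                 TRUE, TRUE, TRUE, TRUE),
               stringsAsFactors = FALSE),
    data.frame(name = c("true_popliteal_angle", "popliteal_angle",
                        "dynamic_popliteal_angle", "dorsiflexion_knee_flexed",
                        "dorsiflexion_knee_extended", "dynamic_dorsiflexion",
                        "hip_abduction_knee_extended", "hip_extension",
                        "duncan_ely_slow", "duncan_ely_fast",
                        "hip_internal_rotation", "hip_external_rotation",
                        "selective_motor_control_ankle"),
               category = "rom_spasticity", type = c(rep("continuous", 12),
                                                     "categorical"),
               side_specific = TRUE, stringsAsFactors = FALSE),
    data.frame(name = c("femoral_anteversion", "tibial_torsion",
                        "thigh_heel_angle", "foot_posture_midfoot",
                        "foot_posture_forefoot", "foot_posture_hindfoot_sagittal",
                        "foot_posture_hindfoot_coronal"),
               category = "bone", type = c(rep("continuous", 3),
                                           rep("categorical", 4)),
               side_specific = TRUE, stringsAsFactors = FALSE)
  )
  if (task == "surgery") {
    keep <- c("age", "height", "weight",
              "hip_abduction_knee_extended", "dorsiflexion_knee_extended",
              "duncan_ely_fast", "true_popliteal_angle", "popliteal_angle",
              "hip_internal_rotation", "hip_external_rotation",
              "tibial_torsion")
    reg <- reg[reg$name %in% keep, ]
    rownames(reg) <- NULL
  }
  reg
}

#' Outcome label registries
#'
#' Names of the frequently occurring binary outcomes modeled per task:
#' clinician-identified musculoskeletal impairments, or surgical procedures.
#'
#' @param task `"impairment"` or `"surgery"`.
#' @return Character vector of outcome names.
#' @export
outcome_registry <- function(task = c("impairment", "surgery")) {
  task <- match.arg(task)
  if (task == "impairment") {
    c("Hamstring spasticity", "Gastrocnemius spasticity",
      "Increased femoral neck anteversion", "Soleus spasticity",
      "Gastrocnemius contracture", "Increased external tibial torsion",
      "Rectus femoris spasticity", "Soleus contracture",
      "Knee fixed flexion deformity", "Gluteal weakness", "Soleus weakness",
      "Hip fixed flexion deformity", "Hamstring contracture",
      "Gastrocnemius weakness")
  } else {
    c("Femoral derotation osteotomy", "Semitendinosus transfer",
      "Gastrocnemius lengthening (Strayer)", "Adductor longus lengthening")
  }
}

#' Read or write examination / label tables
#'
#' Delimited (CSV) tables. Examination tables carry `subject_id`,
#' `session_id`, `side` plus registry columns; missing cells are empty.
#' Label tables carry `session_id`, `side` plus one binary column per
#' outcome.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_exam_table`/`read_label_table` return a data frame.
#' @export
read_exam_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"), check.names = FALSE)
}

#' @rdname read_exam_table
#' @export
write_exam_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_exam_table
#' @export
read_label_table <- function(path) read_exam_table(path)

#' @rdname read_exam_table
#' @export
write_label_table <- function(x, path) write_exam_table(x, path)
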