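# Assembly of per-side modeling records, predictor-completeness and
# outcome-frequency filters, and median/mode imputation.

cohort_attr <- function(table, predictors, features, labels, imputed = NULL) {
  attr(table, "predictor_cols") <- predictors
  attr(table, "feature_cols") <- features
  attr(table, "label_cols") <- labels
  if (!is.null(imputed)) attr(table, "imputed") <- imputed
  class(table) <- unique(c("cohort_table", class(table)))
  table
}

#' Column groups of a cohort table
#' @param table A `cohort_table`.
#' @return List with `predictors` (exam columns), `features` (kinematic
#'   flags) and `labels`.
#' @export
cohort_columns <- function(table) {
  list(predictors = attr(table, "predictor_cols"),
       features = attr(table, "feature_cols"),
       labels = attr(table, "label_cols"))
}

#' Assemble a per-side modeling cohort
#'
#' Joins the extracted kinematic feature vectors, examination predictors and
#' outcome labels on session and side, one row per session-by-side record
#' (each side modeled separately, doubling the data). The task selects the
#' predictor registry and label set. Sessions that cannot be joined are
#' dropped with a message reporting the count.
#'
#' @param trials List of [gait_trial] objects (one per session; trial ids
#'   are the session ids).
#' @param exams Examination data frame (`subject_id`, `session_id`, `side`,
#'   registry columns).
#' @param labels Label data frame (`session_id`, `side`, one binary column
#'   per outcome).
#' @param reference A `reference_set` for feature extraction.
#' @param task `"impairment"` or `"surgery"`.
#' @param control Detector constants.
#' @return A `cohort_table` (data frame with column-group attributes).
#' @export
assemble <- function(trials, exams, labels, reference,
                     task = c("impairment", "surgery"),
                     control = detector_control()) {
  task <- match.arg(task)
  reg <- exam_registry(task)
  outs <- intersect(outcome_registry(task), names(labels))
  feats <- do.call(rbind, lapply(trials, function(tr) {
    fv <- extract_features(tr, reference, control)
    cbind(data.frame(session_id = tr$trial_id, subject_id = tr$subject_id,
                     stringsAsFactors = FALSE), fv)
  }))
  keep_exam <- c("session_id", "side", intersect(reg$name, names(exams)))
  tab <- merge(feats, exams[keep_exam], by = c("session_id", "side"))
  tab <- merge(tab, labels[c("session_id", "side", outs)],
               by = c("session_id", "side"))
  dropped <- nrow(feats) - nrow(tab)
  if (dropped > 0) {
    message(dropped, " record(s) dropped: no matching exam/label rows")
  }
  tab <- tab[order(tab$session_id, tab$side), ]
  rownames(tab) <- NULL
  cohort_attr(tab,
              predictors = intersect(reg$name, names(tab)),
              features = feature_names(),
              labels = outs)
}

#' Drop incompletely collected predictors
#'
#' Removes examination predictor columns that were not collected for at
#' least `threshold` of the children (completeness computed at the child
#' level: a child counts as collected when any of its rows holds a value).
#' Kinematic feature columns are never missing and are always retained.
#'
#' @param table A `cohort_table`.
#' @param threshold Minimum observed fraction of children (default 0.90).
#' @return The filtered `cohort_table`; dropped columns recorded in the
#'   `dropped_predictors` attribute.
#' @export
filter_predictors <- function(table, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  cols <- cohort_columns(table)
  children <- unique(table$subject_id)
  drop <- character(0)
  for (nm in cols$predictors) {
    seen <- tapply(!is.na(table[[nm]]), table$subject_id, any)
    if (mean(seen[children]) < threshold) drop <- c(drop, nm)
  }
  out <- table[setdiff(names(table), drop)]
  out <- cohort_attr(out, setdiff(cols$predictors, drop), cols$features,
                     cols$labels)
  attr(out, "dropped_predictors") <- drop
  attr(out, "dropped_labels") <- attr(table, "dropped_labels")
  out
}

#' Drop infrequent outcomes
#'
#' Removes label columns with fewer than `min_occurrences` positive records.
#'
#' @param table A `cohort_table`.
#' @param min_occurrences Minimum number of positives (default 100).
#' @return The filtered `cohort_table`; dropped labels recorded in the
#'   `dropped_labels` attribute.
#' @export
filter_outcomes <- function(table, min_occurrences = 100) {
  cols <- cohort_columns(table)
  drop <- cols$labels[vapply(cols$labels, function(nm)
    sum(table[[nm]] == 1, na.rm = TRUE) < min_occurrences, logical(1))]
  out <- table[setdiff(names(table), drop)]
  out <- cohort_attr(out, cols$predictors, cols$features,
                     setdiff(cols$labels, drop))
  attr(out, "dropped_labels") <- drop
  attr(out, "dropped_predictors") <- attr(table, "dropped_predictors")
  out
}

#' Impute missing predictor values
#'
#' Continuous predictors are imputed by their median, categorical ones by
#' their most frequent category (ties broken by lexicographic order).
#' Imputation values are fitted on `fit_rows` only and applied everywhere,
#' so a model trained on a bootstrap resample never reads its validation
#' rows. Imputed cells are flagged in the `imputed` attribute (a logical
#' matrix rows-by-predictors).
#'
#' @param table A `cohort_table`.
#' @param fit_rows Integer row indices used to fit the imputation values
#'   (default: all rows).
#' @return The imputed `cohort_table` (no missing predictor values).
#' @export
impute <- function(table, fit_rows = seq_len(nrow(table))) {
  if (length(fit_rows) == 0) stop("fit_rows must be non-empty")
  cols <- cohort_columns(table)
  flags <- matrix(FALSE, nrow(table), length(cols$predictors),
                  dimnames = list(NULL, cols$predictors))
  values <- list()
  for (nm in cols$predictors) {
    x <- table[[nm]]
    fit <- x[fit_rows]
    fit <- fit[!is.na(fit)]
    if (length(fit) == 0) {
      stop("predictor '", nm, "' has no observed value in the fitting rows")
    }
    if (is.numeric(x)) {
      v <- stats::median(fit)
    } else {
      tab <- table(fit)
      v <- sort(names(tab)[tab == max(tab)])[1]
    }
    values[[nm]] <- v
    miss <- is.na(x)
    flags[miss, nm] <- TRUE
    table[[nm]][miss] <- v
  }
  out <- cohort_attr(table, cols$predictors, cols$features, cols$labels,
                     imputed = flags)
  attr(out, "imputation_values") <- values
  out
}

#' Write a cohort with its audit manifest
#'
#' Serializes the cohort as CSV plus a JSON manifest recording dropped
#' columns, imputation values and filter thresholds.
#'
#' @param table A `cohort_table`.
#' @param path CSV output path; the manifest is written next to it with a
#'   `.manifest.json` suffix.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  manifest <- list(
    predictor_cols = cohort_columns(table)$predictors,
    feature_cols = cohort_columns(table)$features,
    label_cols = cohort_columns(table)$labels,
    dropped_predictors = attr(table, "dropped_predictors"),
    dropped_labels = attr(table, "dropped_labels"),
    imputation_values = attr(table, "imputation_values")
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
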