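#' Sweep file dialect
#'
#' Describes how a long-format sweep CSV is laid out.  The acquisition
#' sampling rate is carried as data here rather than assumed: if
#' `sampling_interval_ms` is `NULL` it is inferred from the file and merely
#' checked for uniformity.
#'
#' @param sampling_interval_ms Expected sampling interval in ms, or `NULL`
#'   to infer it.
#' @param time_unit,voltage_unit Units the file is written in; only `"ms"`
#'   and `"uV"` are accepted (conversion from vendor units is out of scope).
#' @param sampling_tol_ms Tolerance for sampling-interval uniformity.
#' @return A list of class `sweep_dialect`.
#' @export
sweep_dialect <- function(sampling_interval_ms = NULL,
                          time_unit = "ms", voltage_unit = "uV",
                          sampling_tol_ms = 1e-9) {
  if (!identical(time_unit, "ms") || !identical(voltage_unit, "uV"))
    stop(errorCondition("unsupported units: time must be ms, voltage uV",
                        class = c("erg_bad_units", "error", "condition")))
  structure(list(sampling_interval_ms = sampling_interval_ms,
                 time_unit = time_unit, voltage_unit = voltage_unit,
                 sampling_tol_ms = sampling_tol_ms),
            class = "sweep_dialect")
}

#' Read a dialect description from a YAML file
#' @param path Path to a YAML file with any of the [sweep_dialect()] fields.
#' @return A `sweep_dialect`.
#' @export
read_sweep_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(sweep_dialect, cfg[intersect(names(cfg),
                                       names(formals(sweep_dialect)))])
}

SWEEP_COLUMNS <- c("animal_id", "eye", "luminance_log", "trial",
                   "time_ms", "voltage_uV")

#' Read long-format ERG sweeps
#'
#' Reads a long-format CSV of flash ERG sweeps (one row per sample) and
#' validates its schema and invariants: the six required columns are present
#' (order-independent), time is strictly increasing and uniformly sampled
#' within each trial, and every trial contains pretrial samples
#' (`time_ms < 0`), so that the pretrial baseline is a pure window query.
#'
#' @param path Path to a CSV with columns `animal_id`, `eye`,
#'   `luminance_log`, `trial`, `time_ms`, `voltage_uV` in any order.
#' @param dialect A [sweep_dialect()].
#' @return A `data.frame` of class `sweep_table` with the six columns in
#'   canonical order.
#' @export
read_sweeps <- function(path, dialect = sweep_dialect()) {
  if (!file.exists(path))
    stop(errorCondition(paste0("file not found: ", path),
                        class = c("erg_missing_file", "error", "condition")))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sweeps(df, dialect)
}

#' Validate a sweep table
#'
#' @param df A data frame with the sweep columns.
#' @param dialect A [sweep_dialect()].
#' @return The validated `sweep_table` (canonical column order).
#' @export
validate_sweeps <- function(df, dialect = sweep_dialect()) {
  missing <- setdiff(SWEEP_COLUMNS, names(df))
  if (length(missing) > 0)
    stop(errorCondition(paste0("missing column(s): ",
                               paste(missing, collapse = ", ")),
                        class = c("erg_missing_column", "error", "condition")))
  df <- df[, SWEEP_COLUMNS]
  df$animal_id <- as.character(df$animal_id)
  df$eye <- as.character(df$eye)
  if (!all(df$eye %in% c("left", "right")))
    stop(errorCondition("eye must be 'left' or 'right'",
                        class = c("erg_bad_eye", "error", "condition")))
  df$trial <- as.integer(df$trial)
  if (any(df$trial < 1L))
    stop(errorCondition("trial indices must be >= 1",
                        class = c("erg_bad_trial", "error", "condition")))

  groups <- group_rows(df$animal_id, df$eye, df$luminance_log, df$trial)
  for (idx in groups) {
    t <- df$time_ms[idx]
    if (any(diff(t) <= 0))
      stop(errorCondition("non-monotone time within a trial",
                          class = c("erg_nonmonotone_time", "error",
                                    "condition")))
    d <- diff(t)
    if (max(d) - min(d) > dialect$sampling_tol_ms)
      stop(errorCondition("non-uniform sampling within a trial",
                          class = c("erg_nonuniform_sampling", "error",
                                    "condition")))
    if (!is.null(dialect$sampling_interval_ms) &&
        abs(mean(d) - dialect$sampling_interval_ms) > dialect$sampling_tol_ms)
      stop(errorCondition(sprintf(
        "sampling interval %.9g ms does not match dialect %.9g ms",
        mean(d), dialect$sampling_interval_ms),
        class = c("erg_nonuniform_sampling", "error", "condition")))
    if (!any(t < 0))
      stop(errorCondition("trial has no pretrial window (no time_ms < 0)",
                          class = c("erg_no_pretrial", "error", "condition")))
  }
  class(df) <- c("sweep_table", "data.frame")
  df
}

#' Write a sweep table
#' @param sweeps A `sweep_table`.
#' @param path Output CSV path.
#' @export
write_sweeps <- function(sweeps, path) {
  df <- as.data.frame(sweeps)[, SWEEP_COLUMNS]
  df$luminance_log <- fmt_num(df$luminance_log)
  df$time_ms <- fmt_num(df$time_ms)
  df$voltage_uV <- fmt_num(df$voltage_uV)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

FEATURE_COLUMNS <- c("animal_id", "eye", "luminance_log", "n_trials",
                     "baseline_uV", "a_amp_uV", "a_implicit_ms",
                     "b_amp_uV", "b_implicit_ms",
                     "op1_implicit_ms", "op2_implicit_ms", "op3_implicit_ms",
                     "op4_implicit_ms",
                     "op1_amp_uV", "op2_amp_uV", "op3_amp_uV", "op4_amp_uV",
                     "a_fallback", "filter_cutoff_hz", "filter_order")

# 6 significant digits, empty string for NA (missing is never written as 0)
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", formatC(x, digits = 6, format = "g"))
  out
}

#' Write an ERG feature table
#'
#' Writes a TSV with fixed column order, 6-significant-digit formatting,
#' deterministic row sort (animal, eye, luminance), and empty cells (never
#' zero) for missing values, so identical tables always produce identical
#' bytes.
#'
#' @param features A `feature_table` as produced by [extract_features()].
#' @param path Output TSV path.
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features)
  missing <- setdiff(FEATURE_COLUMNS, names(df))
  for (m in missing) df[[m]] <- NA
  df <- df[, FEATURE_COLUMNS]
  if (nrow(df) > 0) {
    df <- df[order(df$animal_id, df$eye, df$luminance_log), , drop = FALSE]
    num <- setdiff(FEATURE_COLUMNS, c("animal_id", "eye", "a_fallback"))
    for (col in num) df[[col]] <- fmt_num(as.numeric(df[[col]]))
    df$a_fallback <- ifelse(is.na(df$a_fallback), "",
                            ifelse(as.logical(df$a_fallback), "TRUE", "FALSE"))
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read an ERG feature table written by [write_features()]
#' @param path TSV path.
#' @return A `feature_table` data frame.
#' @export
read_features <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("file not found: ", path),
                        class = c("erg_missing_file", "error", "condition")))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  missing <- setdiff(FEATURE_COLUMNS, names(df))
  if (length(missing) > 0)
    stop(errorCondition(paste0("missing column(s): ",
                               paste(missing, collapse = ", ")),
                        class = c("erg_missing_column", "error", "condition")))
  df <- df[, FEATURE_COLUMNS]
  df$a_fallback <- as.logical(df$a_fallback)
  validate_features(df)
}

#' Validate a feature table
#'
#' Checks that amplitudes are non-negative and that the oscillatory
#' potential implicit times are strictly increasing wherever present.
#'
#' @param df Feature data frame.
#' @return The validated `feature_table`.
#' @export
validate_features <- function(df) {
  amp_cols <- c("a_amp_uV", "b_amp_uV",
                paste0("op", 1:4, "_amp_uV"))
  for (col in intersect(amp_cols, names(df)))
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop(errorCondition(paste0("negative amplitude in ", col),
                          class = c("erg_negative_amplitude", "error",
                                    "condition")))
  op_t <- as.matrix(df[, paste0("op", 1:4, "_implicit_ms")])
  for (i in seq_len(nrow(op_t))) {
    v <- op_t[i, ]
    v <- v[!is.na(v)]
    if (length(v) >= 2 && any(diff(v) <= 0))
      stop(errorCondition("OP implicit times not strictly increasing",
                          class = c("erg_op_order", "error", "condition")))
  }
  class(df) <- unique(c("feature_table", class(df)))
  df
}

#' Read a group summary table (mean / SEM / n)
#'
#' Reads printed summary statistics — one row per factor cell with the cell
#' mean, its standard error, and the sample size — as published in tables of
#' the form "46.0 (1.4)" with an n row.  These summaries are sufficient for
#' a fixed-effects factorial ANOVA (see [summary_stats_anova()]).
#'
#' @param path CSV with columns `factor_a`, `factor_b`, `mean`, `sem`, `n`
#'   and optionally `variable` and `units`.
#' @param require_crossing If `TRUE`, require a complete `factor_a` ×
#'   `factor_b` crossing (needed for factorial analysis).
#' @return A `summary_table` data frame.
#' @export
read_summary <- function(path, require_crossing = FALSE) {
  if (!file.exists(path))
    stop(errorCondition(paste0("file not found: ", path),
                        class = c("erg_missing_file", "error", "condition")))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_summary(df, require_crossing = require_crossing)
}

#' Validate a summary table
#' @inheritParams read_summary
#' @param df Summary data frame.
#' @return The validated `summary_table`.
#' @export
validate_summary <- function(df, require_crossing = FALSE) {
  required <- c("factor_a", "factor_b", "mean", "sem", "n")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(errorCondition(paste0("missing column(s): ",
                               paste(missing, collapse = ", ")),
                        class = c("erg_missing_column", "error", "condition")))
  if (any(!is.finite(df$sem)) || any(df$sem <= 0))
    stop(errorCondition("sem must be positive",
                        class = c("erg_bad_sem", "error", "condition")))
  if (any(df$n != round(df$n)) || any(df$n < 2))
    stop(errorCondition("n must be an integer >= 2",
                        class = c("erg_bad_n", "error", "condition")))
  df$n <- as.integer(df$n)
  if (require_crossing) {
    cells <- table(df$factor_a, df$factor_b)
    if (any(cells != 1))
      stop(errorCondition("incomplete crossing of factor levels",
                          class = c("erg_incomplete_crossing", "error",
                                    "condition")))
  }
  class(df) <- unique(c("summary_table", class(df)))
  df
}
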