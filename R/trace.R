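#' ERG trace container
#'
#' A single stimulus-locked voltage trace.  Time is in milliseconds relative
#' to stimulus onset (pretrial samples are negative), voltage in microvolts.
#'
#' @param time_ms Numeric vector of sample times (ms), strictly increasing.
#' @param voltage_uV Numeric vector of voltages (µV), same length.
#' @param n_trials Number of raw trials this trace represents (1 for a raw
#'   sweep, >1 for an average).
#' @param animal_id,eye,luminance_log Optional provenance fields.
#' @return An object of class `erg_trace`: a list with elements `time_ms`,
#'   `voltage_uV`, `n_trials`, `animal_id`, `eye`, `luminance_log`.
#' @export
erg_trace <- function(time_ms, voltage_uV, n_trials = 1L,
                      animal_id = NA_character_, eye = NA_character_,
                      luminance_log = NA_real_) {
  time_ms <- as.numeric(time_ms)
  voltage_uV <- as.numeric(voltage_uV)
  if (length(time_ms) != length(voltage_uV))
    stop(errorCondition("time and voltage must have equal length",
                        class = c("erg_length_mismatch", "error", "condition")))
  if (length(time_ms) >= 2 && any(diff(time_ms) <= 0))
    stop(errorCondition("non-monotone time",
                        class = c("erg_nonmonotone_time", "error", "condition")))
  structure(list(time_ms = time_ms, voltage_uV = voltage_uV,
                 n_trials = as.integer(n_trials), animal_id = animal_id,
                 eye = eye, luminance_log = luminance_log),
            class = "erg_trace")
}

#' @export
print.erg_trace <- function(x, ...) {
  cat(sprintf("<erg_trace> %d samples, %.3g to %.3g ms, n_trials = %d\n",
              length(x$time_ms), min(x$time_ms), max(x$time_ms), x$n_trials))
  if (!is.na(x$animal_id))
    cat(sprintf("  animal %s, eye %s, luminance %.3g log(cd s/m2)\n",
                x$animal_id, x$eye, x$luminance_log))
  invisible(x)
}

# sampling interval of a trace, asserting uniformity
trace_dt <- function(trace, tol = 1e-9) {
  d <- diff(trace$time_ms)
  if (length(d) == 0) stop("trace has a single sample")
  if (max(d) - min(d) > tol)
    stop(errorCondition("non-uniform sampling",
                        class = c("erg_nonuniform_sampling", "error", "condition")))
  mean(d)
}

# restrict (time, value) pairs to a closed window; returns index vector
window_idx <- function(time_ms, window_ms) {
  which(time_ms >= window_ms[1] & time_ms <= window_ms[2])
}

# split row indices by a composite key (group order unspecified; row order
# within a group preserved).  Integer coding via match plus a stable radix
# sort avoids the string conversions interaction()/factor() would do on
# long tables.
group_rows <- function(...) {
  cols <- list(...)
  codes <- lapply(cols, function(x) match(x, unique(x)))
  id <- codes[[1]]
  if (length(codes) > 1)
    for (k in 2:length(codes))
      id <- (id - 1) * max(codes[[k]]) + codes[[k]]
  ord <- order(id, method = "radix")
  ids <- id[ord]
  n <- length(ids)
  if (n == 0) return(list())
  ends <- c(which(ids[-1] != ids[-n]), n)
  starts <- c(1L, ends[-length(ends)] + 1L)
  lapply(seq_along(starts), function(g) ord[starts[g]:ends[g]])
}
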