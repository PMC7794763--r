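#' High-pass filter specification for oscillatory potential isolation
#'
#' Oscillatory potentials (OPs) — the high-frequency wavelets riding on the
#' rising limb of the b-wave — are isolated with a digital Butterworth
#' high-pass filter at 25 Hz.  The filter is applied forward and backward
#' (zero phase) so that OP implicit times, the latency metric of interest,
#' are not biased by filter group delay.
#'
#' @param cutoff_hz High-pass cutoff frequency (Hz).  Default 25.
#' @param order Filter order for a single pass.  Default 4.
#' @param zero_phase Apply forward–backward (default `TRUE`).  The effective
#'   magnitude response is then the squared single-pass response.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 25, order = 4, zero_phase = TRUE) {
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive")
  if (order < 1) stop("order must be >= 1")
  structure(list(family = "butterworth", mode = "highpass",
                 cutoff_hz = cutoff_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Search windows and thresholds for feature measurement
#'
#' @param a_window_ms Window (ms after stimulus onset) searched for the
#'   a-wave trough.
#' @param b_extra_ms The b-wave search window runs from the a-wave trough to
#'   the end of the trace minus `edge_trim_ms`.
#' @param op_extra_ms OP peaks are searched from the a-wave implicit time to
#'   the b-wave implicit time plus this margin.
#' @param min_prominence_uV Minimum topographic prominence for an OP peak.
#' @param op_detect_lowpass_hz Zero-phase low-pass applied to a copy of the
#'   OP trace before peak detection only (the subtraction path keeps the
#'   pure high-pass), suppressing broadband noise above the OP band as a
#'   band-pass OP isolation would.  `Inf` disables it.
#' @param min_a_amp_uV Below this a-wave amplitude the trough is considered
#'   undetectable (dim flashes); the b-wave is then referenced to
#'   (stimulus onset, baseline) and the row flagged `a_fallback`.
#' @param edge_trim_ms Samples within this distance of the trace edges are
#'   excluded from peak searches (filter edge transients).
#' @param pre_window_ms Baseline window, relative to stimulus onset
#'   (negative times); default the entire pretrial record.
#' @return A list of class `feature_windows`.
#' @export
feature_windows <- function(a_window_ms = c(0, 50), b_extra_ms = NULL,
                            op_extra_ms = 20, min_prominence_uV = 5,
                            min_a_amp_uV = 10, edge_trim_ms = 10,
                            pre_window_ms = c(-Inf, 0),
                            op_detect_lowpass_hz = 300) {
  structure(list(a_window_ms = a_window_ms, op_extra_ms = op_extra_ms,
                 min_prominence_uV = min_prominence_uV,
                 min_a_amp_uV = min_a_amp_uV, edge_trim_ms = edge_trim_ms,
                 pre_window_ms = pre_window_ms,
                 op_detect_lowpass_hz = op_detect_lowpass_hz),
            class = "feature_windows")
}

# zero-phase low-pass used only to stabilise peak detection
lowpass_trace <- function(trace, cutoff_hz) {
  dt <- trace_dt(trace)
  fs <- 1000 / dt
  if (!is.finite(cutoff_hz) || cutoff_hz >= fs / 2) return(trace)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  pad <- reflect_pad_length(length(trace$voltage_uV), fs, cutoff_hz)
  out <- trace
  out$voltage_uV <- filtfilt_reflect(bf$b, bf$a, trace$voltage_uV, pad)
  out
}

#' Average repeated sweeps
#'
#' Repeated trials at one flash luminance are averaged pointwise.  All
#' sweeps must share the same time grid.
#'
#' @param sweeps A list of `erg_trace` objects, or a numeric matrix with one
#'   column per trial (then `time_ms` must be supplied).
#' @param time_ms Time grid when `sweeps` is a matrix.
#' @return An `erg_trace` with `n_trials` set to the number of sweeps.
#' @export
average_sweeps <- function(sweeps, time_ms = NULL) {
  if (is.matrix(sweeps)) {
    if (is.null(time_ms)) stop("time_ms required with a matrix of sweeps")
    if (nrow(sweeps) != length(time_ms))
      stop(errorCondition("grid mismatch",
                          class = c("erg_grid_mismatch", "error", "condition")))
    return(erg_trace(time_ms, rowMeans(sweeps), n_trials = ncol(sweeps)))
  }
  if (length(sweeps) < 1) stop("need at least one sweep")
  t0 <- sweeps[[1]]$time_ms
  for (s in sweeps)
    if (length(s$time_ms) != length(t0) || any(s$time_ms != t0))
      stop(errorCondition("grid mismatch between sweeps",
                          class = c("erg_grid_mismatch", "error", "condition")))
  v <- rowMeans(vapply(sweeps, function(s) s$voltage_uV,
                       numeric(length(t0))))
  tmpl <- sweeps[[1]]
  erg_trace(t0, v, n_trials = length(sweeps), animal_id = tmpl$animal_id,
            eye = tmpl$eye, luminance_log = tmpl$luminance_log)
}

#' Estimate the pretrial baseline
#'
#' Mean voltage over the pretrial window (times < 0).  All amplitude
#' measurements are referenced to this baseline.
#'
#' @param trace An `erg_trace`.
#' @param pre_window_ms Window of (negative) times used; default the whole
#'   pretrial record.
#' @param min_samples Minimum number of pretrial samples required.
#' @return Baseline voltage (µV).
#' @export
estimate_baseline <- function(trace, pre_window_ms = c(-Inf, 0),
                              min_samples = 5) {
  idx <- which(trace$time_ms >= pre_window_ms[1] &
                 trace$time_ms < min(pre_window_ms[2], 0))
  if (length(idx) < min_samples)
    stop(errorCondition("empty or too-short pretrial window",
                        class = c("erg_no_pretrial", "error", "condition")))
  mean(trace$voltage_uV[idx])
}

# odd-reflection padding length: >= 3x the filter impulse scale (fs/cutoff),
# capped at n-1 as with scipy-style filtfilt
reflect_pad_length <- function(n, fs_hz, cutoff_hz) {
  min(n - 1L, as.integer(ceiling(3 * fs_hz / cutoff_hz)))
}

# direct-form ARMA filter (zero initial conditions): MA by one-sided
# convolution, AR by recursion — both at C speed via stats::filter
arma_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  xp <- c(numeric(nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- v[nb:length(v)]
  if (length(a) > 1)
    v <- stats::filter(v, -a[-1], method = "recursive")
  as.numeric(v)
}

# zero-phase (forward-backward) application of an ARMA filter with
# odd-reflection padding at both ends
filtfilt_reflect <- function(b, a, x, pad) {
  n <- length(x)
  if (pad > 0) {
    head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
    tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(head_pad, x, tail_pad)
  } else xp <- x
  y <- arma_filter(b, a, xp)
  y <- rev(arma_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Isolate oscillatory potentials by high-pass filtering
#'
#' Applies the Butterworth high-pass of `filt` to the averaged trace.  With
#' `zero_phase = TRUE` the filter runs forward and backward over an
#' odd-reflection-padded copy of the trace, so passband components keep
#' their peak times and the effective magnitude response is the squared
#' single-pass Butterworth response.
#'
#' @param trace An `erg_trace` (uniformly sampled).
#' @param filt A [filter_spec()].
#' @return An `erg_trace` on the same grid containing the high-pass (OP)
#'   component.
#' @export
isolate_ops <- function(trace, filt = filter_spec()) {
  dt <- trace_dt(trace)
  fs <- 1000 / dt
  nyq <- fs / 2
  if (filt$cutoff_hz >= nyq)
    stop(errorCondition(sprintf("cutoff %.3g Hz >= Nyquist %.3g Hz",
                                filt$cutoff_hz, nyq),
                        class = c("erg_cutoff_nyquist", "error", "condition")))
  bf <- signal::butter(filt$order, filt$cutoff_hz / nyq, type = "high")
  # a high-pass has zero DC gain, so removing the mean first changes only
  # the edge transients; it makes DC rejection exact
  x <- trace$voltage_uV - mean(trace$voltage_uV)
  if (filt$zero_phase) {
    pad <- reflect_pad_length(length(x), fs, filt$cutoff_hz)
    y <- filtfilt_reflect(bf$b, bf$a, x, pad)
  } else {
    y <- arma_filter(bf$b, bf$a, x)
  }
  out <- trace
  out$voltage_uV <- y
  out
}

#' Remove the oscillatory potentials from a trace
#'
#' Pointwise difference; by construction `subtract_ops(trace, op)` plus the
#' OP trace reconstructs the input exactly.
#'
#' @param trace,op_trace `erg_trace` objects on the same grid.
#' @return The OP-subtracted (smooth) `erg_trace`.
#' @export
subtract_ops <- function(trace, op_trace) {
  if (length(trace$time_ms) != length(op_trace$time_ms) ||
      any(trace$time_ms != op_trace$time_ms))
    stop(errorCondition("grid mismatch",
                        class = c("erg_grid_mismatch", "error", "condition")))
  out <- trace
  out$voltage_uV <- trace$voltage_uV - op_trace$voltage_uV
  out
}

#' Measure the a-wave
#'
#' The a-wave amplitude is measured from the pretrial baseline to the most
#' negative point of the (unfiltered) averaged trace in the search window;
#' its implicit time is the latency of that minimum from stimulus onset.
#' Ties resolve to the earliest sample.
#'
#' @param trace The averaged (unfiltered) `erg_trace`.
#' @param baseline_uV Baseline from [estimate_baseline()].
#' @param search_window_ms Window searched for the trough.
#' @return List with `a_amp_uV` (clipped at 0), `a_implicit_ms`,
#'   `trough_uV` (the raw trough voltage).
#' @export
measure_a_wave <- function(trace, baseline_uV, search_window_ms = c(0, 50)) {
  idx <- window_idx(trace$time_ms, search_window_ms)
  if (length(idx) == 0)
    stop(errorCondition("empty a-wave search window",
                        class = c("erg_empty_window", "error", "condition")))
  v <- trace$voltage_uV[idx]
  i <- which.min(v)                      # earliest on ties
  list(a_amp_uV = max(0, baseline_uV - v[i]),
       a_implicit_ms = trace$time_ms[idx[i]],
       trough_uV = v[i])
}

#' Measure the b-wave
#'
#' The b-wave amplitude is measured from the a-wave trough to the highest
#' positive point of the OP-subtracted trace; its implicit time is the
#' latency of that maximum.  Ties resolve to the earliest sample.
#'
#' @param smooth_trace The OP-subtracted `erg_trace`.
#' @param a_trough List or vector with elements `time_ms` and `value_uV`
#'   (trough of the raw average, or the (onset, baseline) fallback).
#' @param search_window_ms Window searched for the peak; defaults to
#'   trough-time to end of trace.
#' @return List with `b_amp_uV` (clipped at 0) and `b_implicit_ms`.
#' @export
measure_b_wave <- function(smooth_trace, a_trough,
                           search_window_ms = NULL) {
  if (is.null(search_window_ms))
    search_window_ms <- c(a_trough$time_ms, max(smooth_trace$time_ms))
  idx <- window_idx(smooth_trace$time_ms, search_window_ms)
  if (length(idx) == 0)
    stop(errorCondition("empty b-wave search window",
                        class = c("erg_empty_window", "error", "condition")))
  v <- smooth_trace$voltage_uV[idx]
  i <- which.max(v)
  list(b_amp_uV = max(0, v[i] - a_trough$value_uV),
       b_implicit_ms = smooth_trace$time_ms[idx[i]])
}

# local maxima with topographic prominence.
# prominence of a peak: height above the higher of the two key saddles,
# i.e. peak - max(min toward the nearest higher peak or edge, each side).
local_peaks <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  d <- diff(v)
  # rising then falling; plateaus resolve to first sample of the plateau
  s <- sign(d)
  # propagate sign through zero runs so flat tops count once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  which(diff(s) < 0) + 1L
}

peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    h <- v[p]
    # walk left until a higher sample or the edge; track the minimum
    left_min <- h
    i <- p - 1L
    while (i >= 1L && v[i] <= h) { left_min <- min(left_min, v[i]); i <- i - 1L }
    if (i < 1L) left_min <- min(left_min, min(v[seq_len(p)]))
    right_min <- h
    i <- p + 1L
    n <- length(v)
    while (i <= n && v[i] <= h) { right_min <- min(right_min, v[i]); i <- i + 1L }
    if (i > n) right_min <- min(right_min, min(v[p:n]))
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect oscillatory potential peaks
#'
#' Finds positive local maxima of the high-pass (OP) trace inside the
#' search window, filters them by topographic prominence, orders them by
#' time and retains the first four (OP1–OP4).  Fewer than four detected
#' peaks yield missing entries, never zeros.
#'
#' @param op_trace High-pass trace from [isolate_ops()].
#' @param search_window_ms Window searched (already edge-trimmed by the
#'   caller, see [feature_windows()]).
#' @param min_prominence_uV Minimum prominence (µV).
#' @param max_peaks Number of peaks retained.
#' @return Data frame with columns `op`, `implicit_ms`, `amp_uV` (0 rows if
#'   no peak qualifies).
#' @export
detect_op_peaks <- function(op_trace, search_window_ms,
                            min_prominence_uV = 5, max_peaks = 4) {
  idx <- window_idx(op_trace$time_ms, search_window_ms)
  empty <- data.frame(op = integer(0), implicit_ms = numeric(0),
                      amp_uV = numeric(0))
  if (length(idx) < 3) return(empty)
  v <- op_trace$voltage_uV[idx]
  pk <- local_peaks(v)
  pk <- pk[v[pk] > 0]
  if (length(pk) == 0) return(empty)
  prom <- peak_prominence(v, pk)
  pk <- pk[prom >= min_prominence_uV]
  if (length(pk) == 0) return(empty)
  pk <- pk[order(op_trace$time_ms[idx][pk])][seq_len(min(max_peaks,
                                                         length(pk)))]
  data.frame(op = seq_along(pk),
             implicit_ms = op_trace$time_ms[idx][pk],
             amp_uV = v[pk])
}

#' Select the analysed eye for one animal
#'
#' The eye with the larger b-wave amplitude at the comparison luminance
#' (default: the animal's maximal flash luminance) is used; ties break
#' deterministically to the right eye.
#'
#' @param features A `feature_table` restricted to one animal (one or both
#'   eyes).
#' @param comparison_luminance Luminance at which b-wave amplitudes are
#'   compared; default the maximum present.
#' @return List with `eye` (the chosen label) and `features` (that eye's
#'   rows).
#' @export
select_eye <- function(features, comparison_luminance = NULL) {
  df <- as.data.frame(features)
  if (length(unique(df$animal_id)) != 1)
    stop("select_eye expects features for a single animal")
  if (is.null(comparison_luminance))
    comparison_luminance <- max(df$luminance_log)
  at <- df[df$luminance_log == comparison_luminance, ]
  at <- at[!is.na(at$b_amp_uV), ]
  if (nrow(at) == 0)
    stop(errorCondition("no eye has a b-wave at the comparison luminance",
                        class = c("erg_no_bwave", "error", "condition")))
  eyes <- unique(at$eye)
  if (length(eyes) == 1) {
    chosen <- eyes
  } else {
    b <- vapply(c("left", "right"),
                function(e) at$b_amp_uV[at$eye == e][1], numeric(1))
    chosen <- if (b["left"] > b["right"]) "left" else "right"  # tie -> right
  }
  list(eye = chosen, features = df[df$eye == chosen, , drop = FALSE])
}

#' Apply eye selection across a cohort feature table
#' @param features A `feature_table` with one or two eyes per animal.
#' @param comparison_luminance Passed to [select_eye()].
#' @return The feature table restricted to each animal's selected eye.
#' @export
select_eyes <- function(features, comparison_luminance = NULL) {
  df <- as.data.frame(features)
  parts <- lapply(split(df, df$animal_id), function(d)
    select_eye(d, comparison_luminance)$features)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- unique(c("feature_table", class(out)))
  out
}

# feature extraction for one (animal, eye, luminance) group given the
# common time grid and a matrix of trials (columns)
extract_one <- function(time_ms, trials, filt, windows,
                        animal_id = NA_character_, eye = NA_character_,
                        luminance_log = NA_real_) {
  avg <- average_sweeps(trials, time_ms = time_ms)
  avg$animal_id <- animal_id; avg$eye <- eye; avg$luminance_log <- luminance_log
  baseline <- estimate_baseline(avg, windows$pre_window_ms)
  op <- isolate_ops(avg, filt)
  smooth <- subtract_ops(avg, op)

  aw <- measure_a_wave(avg, baseline, windows$a_window_ms)
  a_fallback <- aw$a_amp_uV < windows$min_a_amp_uV
  trough <- if (a_fallback) {
    list(time_ms = 0, value_uV = baseline)
  } else {
    list(time_ms = aw$a_implicit_ms, value_uV = aw$trough_uV)
  }

  t_end <- max(time_ms) - windows$edge_trim_ms
  bw <- measure_b_wave(smooth, trough, c(trough$time_ms, t_end))

  op_window <- c(max(trough$time_ms, min(time_ms) + windows$edge_trim_ms),
                 min(bw$b_implicit_ms + windows$op_extra_ms, t_end))
  op_det <- lowpass_trace(op, windows$op_detect_lowpass_hz)
  peaks <- detect_op_peaks(op_det, op_window, windows$min_prominence_uV)

  op_t <- rep(NA_real_, 4); op_a <- rep(NA_real_, 4)
  if (nrow(peaks) > 0) {
    op_t[seq_len(nrow(peaks))] <- peaks$implicit_ms
    op_a[seq_len(nrow(peaks))] <- peaks$amp_uV
  }
  list(animal_id = animal_id, eye = eye,
       num = c(luminance_log = luminance_log, n_trials = ncol(trials),
               baseline_uV = baseline, a_amp_uV = aw$a_amp_uV,
               a_implicit_ms = if (a_fallback) NA_real_ else aw$a_implicit_ms,
               b_amp_uV = bw$b_amp_uV, b_implicit_ms = bw$b_implicit_ms,
               op1_implicit_ms = op_t[1], op2_implicit_ms = op_t[2],
               op3_implicit_ms = op_t[3], op4_implicit_ms = op_t[4],
               op1_amp_uV = op_a[1], op2_amp_uV = op_a[2],
               op3_amp_uV = op_a[3], op4_amp_uV = op_a[4],
               filter_cutoff_hz = filt$cutoff_hz,
               filter_order = filt$order),
       a_fallback = a_fallback)
}

#' Extract ERG features from a sweep table
#'
#' For every (animal, eye, luminance) group: average the repeated trials,
#' estimate the pretrial baseline, isolate the OPs by zero-phase high-pass
#' filtering, measure the a-wave on the unfiltered average, subtract the
#' OPs and measure the b-wave on the smooth trace, then detect OP1–OP4 on
#' the filtered trace.  Provenance (trial count, filter settings, a-wave
#' fallback) is recorded per row.
#'
#' @param sweeps A `sweep_table` from [read_sweeps()] or
#'   [simulate_cohort()].
#' @param filt A [filter_spec()].
#' @param windows A [feature_windows()].
#' @return A `feature_table` data frame, one row per
#'   (animal, eye, luminance), sorted.
#' @export
extract_features <- function(sweeps, filt = filter_spec(),
                             windows = feature_windows()) {
  df <- as.data.frame(sweeps)
  rows <- lapply(group_rows(df$animal_id, df$eye, df$luminance_log),
                 function(idx) {
    time_ms <- df$time_ms[idx]; volt <- df$voltage_uV[idx]
    tr <- df$trial[idx]
    f <- match(tr, unique(tr))
    ntr <- max(f)
    bad <- length(idx) %% ntr != 0
    if (!bad) {
      # row order within the table is immaterial: sort by trial, then time
      ord <- order(f, time_ms, method = "radix")
      n_samp <- length(idx) %/% ntr
      tmat <- matrix(time_ms[ord], n_samp, ntr)
      bad <- any(tmat != tmat[, 1])
    }
    if (bad)
      stop(errorCondition(
        sprintf("grid mismatch in animal %s eye %s luminance %g",
                df$animal_id[idx[1]], df$eye[idx[1]],
                df$luminance_log[idx[1]]),
        class = c("erg_grid_mismatch", "error", "condition")))
    t0 <- tmat[, 1]
    mat <- matrix(volt[ord], n_samp, ntr)
    extract_one(t0, mat, filt, windows, df$animal_id[idx[1]],
                df$eye[idx[1]], df$luminance_log[idx[1]])
  })
  num <- t(vapply(rows, `[[`, numeric(17), "num"))
  out <- data.frame(
    animal_id = vapply(rows, `[[`, character(1), "animal_id"),
    eye = vapply(rows, `[[`, character(1), "eye"),
    num,
    a_fallback = vapply(rows, `[[`, logical(1), "a_fallback"),
    stringsAsFactors = FALSE)
  out <- out[order(out$animal_id, out$eye, out$luminance_log),
             c("animal_id", "eye", FEATURE_COLUMNS[3:17], "a_fallback",
               "filter_cutoff_hz", "filter_order")]
  rownames(out) <- NULL
  validate_features(out)
}

#' Luminance–response series and maximum a-wave amplitude
#'
#' Per animal (after eye selection) returns the a- and b-wave amplitudes as
#' a function of flash luminance, sorted by luminance, together with the
#' maximum a-wave amplitude over the luminance series — the quantity used
#' to compare outer-retinal function across groups.
#'
#' @param features A `feature_table` (typically after [select_eyes()]).
#' @return List with `series` (animal_id, eye, luminance_log, a_amp_uV,
#'   b_amp_uV, sorted) and `summary` (per animal: `max_a_amp_uV` and the
#'   luminance at which it occurs, and `max_b_amp_uV`).
#' @export
luminance_response <- function(features) {
  df <- as.data.frame(features)
  series <- df[order(df$animal_id, df$luminance_log),
               c("animal_id", "eye", "luminance_log", "a_amp_uV", "b_amp_uV")]
  rownames(series) <- NULL
  summ <- do.call(rbind, lapply(split(series, series$animal_id), function(d) {
    i <- which.max(d$a_amp_uV)
    data.frame(animal_id = d$animal_id[1],
               max_a_amp_uV = d$a_amp_uV[i],
               max_a_luminance_log = d$luminance_log[i],
               max_b_amp_uV = max(d$b_amp_uV),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(series = series, summary = summ)
}
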