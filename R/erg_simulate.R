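#' Synthetic scotopic ERG generator parameters
#'
#' The synthetic dark-adapted flash ERG is a sum of three components on a
#' uniform time grid: a negative a-wave lobe and a slower positive b-wave
#' lobe, each a unit-peak gamma kernel, plus oscillatory potentials
#' modelled as an exponentially damped sinusoid gated at its onset, with
#' additive white Gaussian noise and optional linear drift.  Component
#' amplitudes scale with flash strength through a saturating
#' (semisaturation) law on linear luminance.
#'
#' Defaults describe a bright-flash rodent scotopic ERG: 150 µV a-wave
#' troughing at 15 ms, 450 µV b-wave peaking at 60 ms, 40 µV OPs at 100 Hz
#' starting at 20 ms with a 25 ms decay constant, 10 µV noise, 2 kHz
#' sampling.
#'
#' @param a_amp_uV,a_peak_ms,a_shape a-wave amplitude (µV), trough time
#'   (ms) and gamma shape (>1; larger is narrower).
#' @param b_amp_uV,b_peak_ms,b_shape b-wave parameters, as above.
#' @param op_amp_uV,op_freq_hz,op_onset_ms,op_decay_ms OP amplitude,
#'   frequency (must stay above any analysis high-pass cutoff), onset and
#'   exponential decay constant.
#' @param noise_sd_uV Additive white-noise standard deviation.
#' @param drift_uV_per_s Linear drift slope.
#' @param sampling_interval_ms Sample spacing; the implied rate must be at
#'   least four times `op_freq_hz`.
#' @param pretrial_ms,posttrial_ms Extent of the grid before/after onset.
#' @param luminance_levels Flash strengths, log10(cd·s/m²); dimmest first.
#' @param amp_semisaturation Semisaturation constant (cd·s/m², linear) of
#'   the amplitude-vs-luminance law `I / (I + k)`.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(a_amp_uV = 150, a_peak_ms = 15, a_shape = 6,
                       b_amp_uV = 450, b_peak_ms = 60, b_shape = 8,
                       op_amp_uV = 40, op_freq_hz = 100, op_onset_ms = 20,
                       op_decay_ms = 25,
                       noise_sd_uV = 10, drift_uV_per_s = 0,
                       sampling_interval_ms = 0.5,
                       pretrial_ms = 50, posttrial_ms = 250,
                       luminance_levels = c(-2.4, -1.8, -1.2, -0.6, -0.01),
                       amp_semisaturation = 0.05) {
  p <- structure(as.list(environment()), class = "sim_params")
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  amps <- c(p$a_amp_uV, p$b_amp_uV, p$op_amp_uV)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  if (p$a_shape <= 1 || p$b_shape <= 1) stop("gamma shapes must be > 1")
  fs <- 1000 / p$sampling_interval_ms
  if (fs < 4 * p$op_freq_hz)
    stop(sprintf("sampling rate %.3g Hz must be >= 4x op_freq_hz %.3g Hz",
                 fs, p$op_freq_hz))
  if (p$noise_sd_uV < 0) stop("noise_sd_uV must be >= 0")
  invisible(p)
}

# unit-peak gamma kernel: g(tp) = 1, g(0) = 0
gamma_kernel <- function(t, peak_ms, shape) {
  out <- numeric(length(t))
  pos <- t > 0
  r <- t[pos] / peak_ms
  out[pos] <- r^(shape - 1) * exp((shape - 1) * (1 - r))
  out
}

# damped sinusoid gated at onset; t in ms, freq in Hz
op_kernel <- function(t, freq_hz, onset_ms, decay_ms) {
  out <- numeric(length(t))
  on <- t >= onset_ms
  tt <- t[on] - onset_ms
  out[on] <- exp(-tt / decay_ms) * sin(2 * pi * freq_hz * tt / 1000)
  out
}

# saturating amplitude scale in [0, 1) for a log10 luminance
luminance_scale <- function(luminance_log, semisaturation) {
  i <- 10^luminance_log
  i / (i + semisaturation)
}

sim_grid <- function(p) {
  seq(-p$pretrial_ms, p$posttrial_ms, by = p$sampling_interval_ms)
}

# noiseless composite components on an arbitrary grid
sim_components <- function(p, luminance_log, t) {
  s <- luminance_scale(luminance_log, p$amp_semisaturation)
  list(ab = -p$a_amp_uV * s * gamma_kernel(t, p$a_peak_ms, p$a_shape) +
         p$b_amp_uV * s * gamma_kernel(t, p$b_peak_ms, p$b_shape),
       op = p$op_amp_uV * s * op_kernel(t, p$op_freq_hz, p$op_onset_ms,
                                        p$op_decay_ms))
}

#' Synthesise one ERG sweep
#'
#' @param p A [sim_params()].
#' @param luminance_log Flash strength, log10(cd·s/m²).
#' @param trial_seed Integer seed for this trial's noise; `NULL` uses the
#'   current RNG state.  The same seed always yields the same trace.
#' @return An `erg_trace`.
#' @export
synth_sweep <- function(p, luminance_log, trial_seed = NULL) {
  validate_sim_params(p)
  t <- sim_grid(p)
  comp <- sim_components(p, luminance_log, t)
  v <- comp$ab + comp$op + p$drift_uV_per_s * t / 1000
  if (p$noise_sd_uV > 0) {
    if (!is.null(trial_seed)) set.seed(as.integer(trial_seed))
    v <- v + stats::rnorm(length(t), 0, p$noise_sd_uV)
  }
  erg_trace(t, v, n_trials = 1L, luminance_log = luminance_log)
}

#' Analytic ground-truth features of the noiseless composite
#'
#' Computes the features the extraction pipeline targets, directly from the
#' noiseless composite by exhaustive search on a 10x-oversampled grid (no
#' filtering is involved): a-wave trough from the full composite, b-wave
#' peak from the OP-free (a+b) composite referenced to that trough, and the
#' first four positive peaks of the OP component.  Ground truth is by
#' construction independent of `noise_sd_uV` and `drift_uV_per_s`, and uses
#' the same search windows and dim-flash fallback rule as the pipeline.
#'
#' @param p A [sim_params()].
#' @param luminance_log Flash strength.
#' @param windows A [feature_windows()].
#' @param oversample Grid refinement factor (default 10).
#' @return One-row data frame with the feature columns of a
#'   `feature_table`.
#' @export
ground_truth <- function(p, luminance_log, windows = feature_windows(),
                         oversample = 10) {
  dt <- p$sampling_interval_ms / oversample
  t <- seq(-p$pretrial_ms, p$posttrial_ms, by = dt)
  comp <- sim_components(p, luminance_log, t)
  full <- comp$ab + comp$op

  ai <- window_idx(t, windows$a_window_ms)
  j <- ai[which.min(full[ai])]
  a_amp <- max(0, -full[j]); a_t <- t[j]
  a_fallback <- a_amp < windows$min_a_amp_uV
  trough_t <- if (a_fallback) 0 else a_t
  trough_v <- if (a_fallback) 0 else full[j]

  t_end <- max(t) - windows$edge_trim_ms
  bi <- window_idx(t, c(trough_t, t_end))
  k <- bi[which.max(comp$ab[bi])]
  b_amp <- max(0, comp$ab[k] - trough_v); b_t <- t[k]

  op_window <- c(max(trough_t, min(t) + windows$edge_trim_ms),
                 min(b_t + windows$op_extra_ms, t_end))
  oi <- window_idx(t, op_window)
  pk <- local_peaks(comp$op[oi])
  pk <- pk[comp$op[oi][pk] > 0]
  if (length(pk) > 0) {
    prom <- peak_prominence(comp$op[oi], pk)
    pk <- pk[prom >= windows$min_prominence_uV]
  }
  pk <- pk[seq_len(min(4, length(pk)))]

  row <- data.frame(luminance_log = luminance_log,
                    baseline_uV = 0,
                    a_amp_uV = a_amp,
                    a_implicit_ms = if (a_fallback) NA_real_ else a_t,
                    b_amp_uV = b_amp, b_implicit_ms = b_t,
                    a_fallback = a_fallback)
  for (m in 1:4) {
    row[[paste0("op", m, "_implicit_ms")]] <-
      if (m <= length(pk)) t[oi][pk[m]] else NA_real_
    row[[paste0("op", m, "_amp_uV")]] <-
      if (m <= length(pk)) comp$op[oi][pk[m]] else NA_real_
  }
  row
}

#' Per-cell effect specification for cohort simulation
#'
#' One row per (genotype, treatment) cell of the factorial design, holding
#' multiplicative a-/b-wave amplitude factors, an additive OP delay, and
#' between-animal variability: amplitude factors vary across animals as
#' lognormal multipliers (coefficient of variation `a_cv`/`b_cv`, keeping
#' factors positive), OP delay as additive Gaussian with SD
#' `op_delay_sd_ms`.
#'
#' @param genotypes,treatments Factor levels (2 each for the standard
#'   design).
#' @param b_factor,a_factor,op_delay_ms,b_cv,a_cv,op_delay_sd_ms Scalars
#'   recycled to every cell; edit rows or use [set_cell_effect()] to make a
#'   cell differ.
#' @return Data frame of class `effect_spec` with one row per cell.
#' @export
effect_spec <- function(genotypes = c("control", "diabetic"),
                        treatments = c("vehicle", "fenofibrate"),
                        b_factor = 1, a_factor = 1, op_delay_ms = 0,
                        b_cv = 0.1, a_cv = 0.1, op_delay_sd_ms = 0.5) {
  cells <- expand.grid(genotype = genotypes, treatment = treatments,
                       stringsAsFactors = FALSE)
  cells$b_factor <- b_factor
  cells$a_factor <- a_factor
  cells$op_delay_ms <- op_delay_ms
  cells$b_cv <- b_cv
  cells$a_cv <- a_cv
  cells$op_delay_sd_ms <- op_delay_sd_ms
  if (any(cells$b_factor <= 0) || any(cells$a_factor <= 0))
    stop("effect factors must be > 0")
  class(cells) <- unique(c("effect_spec", class(cells)))
  cells
}

#' Modify one cell of an effect specification
#' @param spec An [effect_spec()].
#' @param genotype,treatment Cell selectors.
#' @param ... Named effect fields to overwrite in that cell.
#' @return The modified `effect_spec`.
#' @export
set_cell_effect <- function(spec, genotype, treatment, ...) {
  i <- which(spec$genotype == genotype & spec$treatment == treatment)
  if (length(i) != 1) stop("unknown cell")
  for (nm in names(list(...))) spec[i, nm] <- list(...)[[nm]]
  if (any(spec$b_factor <= 0) || any(spec$a_factor <= 0))
    stop("effect factors must be > 0")
  spec
}

#' Factorial cohort design
#' @param n_per_cell Animals per (genotype, treatment) cell (>= 2).
#' @param genotypes,treatments Factor levels.
#' @return Data frame with one row per cell and its `n`.
#' @export
cohort_design <- function(n_per_cell = 10,
                          genotypes = c("control", "diabetic"),
                          treatments = c("vehicle", "fenofibrate")) {
  if (any(n_per_cell < 2)) stop("n_per_cell must be >= 2")
  d <- expand.grid(genotype = genotypes, treatment = treatments,
                   stringsAsFactors = FALSE)
  d$n <- n_per_cell
  d
}

# deterministic sub-seed stream: master seed plus a running counter, kept
# inside 32-bit integer range so any single sweep is regenerable
sub_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter) %% 2147483647)
}

# trials per luminance: 10 repeats for the dimmer half of the luminance
# range, 5 for the brighter half
trials_for_luminance <- function(luminance_log, levels) {
  mid <- (min(levels) + max(levels)) / 2
  ifelse(luminance_log <= mid, 10L, 5L)
}

#' Simulate a factorial ERG cohort
#'
#' Draws per-animal effect multipliers for each design cell, applies a
#' small independent per-eye jitter (both eyes are recorded per animal),
#' and synthesises repeated sweeps at every luminance: 10 repeats for the
#' dimmer half of the luminance range and 5 for the brighter half.  All
#' randomness streams from a single master seed through a documented
#' counter scheme, so the output is reproducible byte-for-byte.
#'
#' @param design A [cohort_design()].
#' @param base A [sim_params()] describing the control waveform.
#' @param effects An [effect_spec()].
#' @param seed Master integer seed.
#' @param eye_cv Multiplicative lognormal CV of per-eye amplitude jitter.
#' @param eye_onset_sd_ms SD of per-eye OP onset jitter.
#' @param compute_truth If `TRUE` also return per-(animal, eye, luminance)
#'   ground-truth features (slower; disable for large sweeps of runs).
#' @param windows A [feature_windows()] used for ground truth.
#' @return List with `sweeps` (a `sweep_table`), `animals` (animal_id,
#'   genotype, treatment and drawn per-animal factors), and `truth` (ground
#'   truth features, or `NULL`).
#' @export
simulate_cohort <- function(design = cohort_design(), base = sim_params(),
                            effects = effect_spec(), seed = 1,
                            eye_cv = 0.03, eye_onset_sd_ms = 0.2,
                            compute_truth = TRUE,
                            windows = feature_windows()) {
  if (any(design$n < 2)) stop("invalid design: n per cell must be >= 2")
  counter <- 0L
  sweep_parts <- list()
  truth_parts <- list()
  animal_rows <- list()
  t_grid <- sim_grid(base)
  n_samp <- length(t_grid)

  for (ci in seq_len(nrow(design))) {
    g <- design$genotype[ci]; trt <- design$treatment[ci]
    eff <- effects[effects$genotype == g & effects$treatment == trt, ]
    if (nrow(eff) != 1) stop("invalid design: cell missing from effect_spec")
    for (ai in seq_len(design$n[ci])) {
      animal <- sprintf("%s.%s.%02d", g, trt, ai)
      counter <- counter + 1L
      set.seed(sub_seed(seed, counter))
      a_f <- eff$a_factor * stats::rlnorm(1, 0, eff$a_cv)
      b_f <- eff$b_factor * stats::rlnorm(1, 0, eff$b_cv)
      d_op <- eff$op_delay_ms + stats::rnorm(1, 0, eff$op_delay_sd_ms)
      animal_rows[[animal]] <- data.frame(
        animal_id = animal, genotype = g, treatment = trt,
        a_factor = a_f, b_factor = b_f, op_delay_ms = d_op,
        stringsAsFactors = FALSE)
      for (eye in c("left", "right")) {
        counter <- counter + 1L
        set.seed(sub_seed(seed, counter))
        jit <- stats::rlnorm(2, 0, eye_cv)
        onset_jit <- stats::rnorm(1, 0, eye_onset_sd_ms)
        pe <- base
        pe$a_amp_uV <- base$a_amp_uV * a_f * jit[1]
        pe$b_amp_uV <- base$b_amp_uV * b_f * jit[2]
        pe$op_amp_uV <- base$op_amp_uV * b_f * jit[2]
        pe$op_onset_ms <- base$op_onset_ms + d_op + onset_jit
        for (lum in base$luminance_levels) {
          ntr <- trials_for_luminance(lum, base$luminance_levels)
          comp <- sim_components(pe, lum, t_grid)
          clean <- comp$ab + comp$op + pe$drift_uV_per_s * t_grid / 1000
          vmat <- matrix(clean, nrow = n_samp, ncol = ntr)
          if (pe$noise_sd_uV > 0) {
            for (tr in seq_len(ntr)) {
              counter <- counter + 1L
              set.seed(sub_seed(seed, counter))
              vmat[, tr] <- vmat[, tr] +
                stats::rnorm(n_samp, 0, pe$noise_sd_uV)
            }
          } else counter <- counter + ntr
          sweep_parts[[length(sweep_parts) + 1L]] <- list(
            animal_id = animal, eye = eye, luminance_log = lum,
            ntr = ntr, voltage_uV = as.vector(vmat))
          if (compute_truth) {
            gt <- ground_truth(pe, lum, windows)
            gt <- cbind(data.frame(animal_id = animal, eye = eye,
                                   stringsAsFactors = FALSE), gt)
            truth_parts[[length(truth_parts) + 1L]] <- gt
          }
        }
      }
    }
  }
  blk_n <- vapply(sweep_parts, function(b) b$ntr * n_samp, numeric(1))
  sweeps <- data.frame(
    animal_id = rep(vapply(sweep_parts, `[[`, character(1), "animal_id"),
                    blk_n),
    eye = rep(vapply(sweep_parts, `[[`, character(1), "eye"), blk_n),
    luminance_log = rep(vapply(sweep_parts, `[[`, numeric(1),
                               "luminance_log"), blk_n),
    trial = unlist(lapply(sweep_parts, function(b)
      rep(seq_len(b$ntr), each = n_samp))),
    time_ms = unlist(lapply(sweep_parts, function(b)
      rep(t_grid, b$ntr))),
    voltage_uV = unlist(lapply(sweep_parts, `[[`, "voltage_uV")),
    stringsAsFactors = FALSE)
  class(sweeps) <- c("sweep_table", "data.frame")
  list(sweeps = sweeps,
       animals = do.call(rbind, c(animal_rows, list(make.row.names = FALSE))),
       truth = if (compute_truth) do.call(rbind, truth_parts) else NULL)
}
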