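# narrow gaussian bump: used to build composites with non-overlapping lobes
bump <- function(t, center, width) exp(-((t - center) / width)^2)

test_that("averaging is the pointwise mean with n_trials recorded", {
  t <- seq(-20, 100, by = 0.5)
  v <- sin(t / 10)
  same <- lapply(1:4, function(i) erg_trace(t, v))
  avg <- average_sweeps(same)
  expect_equal(avg$voltage_uV, v)
  expect_equal(avg$n_trials, 4L)

  opp <- average_sweeps(list(erg_trace(t, v), erg_trace(t, -v)))
  expect_equal(opp$voltage_uV, rep(0, length(t)))

  t2 <- t + 0.25
  expect_error(average_sweeps(list(erg_trace(t, v), erg_trace(t2, v))),
               class = "erg_grid_mismatch")
})

test_that("averaging n noisy sweeps shrinks noise like 1/sqrt(n)", {
  t <- seq(-20, 200, by = 0.5)
  template <- 100 * bump(t, 60, 20)
  set.seed(41)
  sweeps <- lapply(1:10, function(i)
    erg_trace(t, template + rnorm(length(t), 0, 10)))
  avg <- average_sweeps(sweeps)
  resid_sd <- sd(avg$voltage_uV - template)
  expect_lt(abs(resid_sd - 10 / sqrt(10)), 0.2 * 10 / sqrt(10))
})

test_that("baseline is the exact mean of the pretrial window", {
  t <- seq(-50, 100, by = 0.5)
  z <- erg_trace(t, rep(0, length(t)))
  expect_equal(estimate_baseline(z), 0)
  expect_equal(estimate_baseline(erg_trace(t, rep(0, length(t)) + 20)), 20)

  set.seed(5)
  v <- rnorm(length(t))
  tr <- erg_trace(t, v)
  expect_identical(estimate_baseline(tr, c(-30, 0)),
                   mean(v[t >= -30 & t < 0]))
  expect_error(estimate_baseline(tr, c(-0.4, 0)), class = "erg_no_pretrial")
})

test_that("the high-pass rejects DC exactly and rejects bad cutoffs", {
  t <- seq(-50, 400, by = 0.5)
  dc <- erg_trace(t, rep(13.7, length(t)))
  expect_lt(max(abs(isolate_ops(dc)$voltage_uV)), 1e-6)
  expect_error(isolate_ops(dc, filter_spec(cutoff_hz = 1500)),
               class = "erg_cutoff_nyquist")
})

test_that("two-pass magnitude matches the analytic Butterworth response", {
  t <- seq(-50, 450, by = 0.5)
  mid <- t > 50 & t < 350          # steady-state region
  for (f in c(5, 10, 50, 100, 200)) {
    x <- sin(2 * pi * f * t / 1000)
    y <- isolate_ops(erg_trace(t, x), filter_spec())$voltage_uV
    gain <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
    expected <- 1 / (1 + (25 / f)^8)   # |H|^2 of the order-4 high-pass
    if (expected > 0.01) {
      expect_lt(abs(gain - expected) / expected, 0.01)
    } else {
      expect_lt(gain, 0.01)
    }
  }
})

test_that("zero-phase filtering leaves passband peak times in place", {
  t <- seq(-50, 450, by = 0.5)
  for (f in c(50, 100, 200)) {
    x <- sin(2 * pi * f * t / 1000)
    y <- isolate_ops(erg_trace(t, x), filter_spec())$voltage_uV
    raw_pk <- t[t >= 200][which.max(x[t >= 200][1:(2 * 1000 / f)])]
    near <- which(abs(t - raw_pk) <= 1000 / f / 3)
    filt_pk <- t[near][which.max(y[near])]
    expect_lt(abs(filt_pk - raw_pk), 0.1)
  }
})

test_that("OP subtraction conserves the trace and recovers the smooth part", {
  t <- seq(-50, 300, by = 0.5)
  set.seed(17)
  v <- 300 * bump(t, 60, 25) + rnorm(length(t), 0, 10)
  tr <- erg_trace(t, v)

  zero_op <- erg_trace(t, rep(0, length(t)))
  expect_equal(subtract_ops(tr, zero_op)$voltage_uV, v)

  op <- isolate_ops(tr)
  smooth <- subtract_ops(tr, op)
  expect_lt(max(abs(smooth$voltage_uV + op$voltage_uV - v)), 1e-9)

  # composite with 100 Hz OPs riding on lobes whose spectrum lies below the
  # cutoff: the smooth trace tracks the OP-free part pointwise
  t2 <- seq(-60, 350, by = 0.5)
  ab <- -150 * bump(t2, 40, 28) + 300 * bump(t2, 120, 40)
  ops <- 40 * ifelse(t2 >= 45, exp(-(t2 - 45) / 25) *
                       sin(2 * pi * 100 * (t2 - 45) / 1000), 0)
  tr2 <- erg_trace(t2, ab + ops)
  sm2 <- subtract_ops(tr2, isolate_ops(tr2))
  inner2 <- t2 > -50 & t2 < 340
  expect_lt(max(abs(sm2$voltage_uV[inner2] - ab[inner2])), 5)
})

test_that("a-wave is measured baseline-to-trough on the raw average", {
  t <- seq(-20, 100, by = 0.5)
  flat <- erg_trace(t, rep(0, length(t)))
  m <- measure_a_wave(flat, 0, c(0, 50))
  expect_equal(m$a_amp_uV, 0)
  expect_equal(m$a_implicit_ms, 0)     # tie-break: earliest sample

  v <- -150 * bump(t, 15, 4)
  m <- measure_a_wave(erg_trace(t, v), 0, c(0, 50))
  expect_equal(m$a_amp_uV, 150, tolerance = 1e-6)
  expect_lt(abs(m$a_implicit_ms - 15), 0.5 + 1e-12)

  shifted <- measure_a_wave(erg_trace(t, v + 20), 20, c(0, 50))
  expect_equal(shifted$a_amp_uV, 150, tolerance = 1e-6)
  expect_error(measure_a_wave(flat, 0, c(200, 300)),
               class = "erg_empty_window")
})

test_that("b-wave is measured trough-to-peak on the OP-subtracted trace", {
  t <- seq(-20, 150, by = 0.5)
  flat <- erg_trace(t, rep(0, length(t)))
  m <- measure_b_wave(flat, list(time_ms = 0, value_uV = 0))
  expect_equal(m$b_amp_uV, 0)
  expect_equal(m$b_implicit_ms, 0)

  ab <- -150 * bump(t, 15, 4) + 300 * bump(t, 60, 12)
  trough <- measure_a_wave(erg_trace(t, ab), 0, c(0, 40))
  m <- measure_b_wave(erg_trace(t, ab),
                      list(time_ms = trough$a_implicit_ms,
                           value_uV = trough$trough_uV))
  expect_equal(m$b_amp_uV, 450, tolerance = 1e-3)
  expect_lt(abs(m$b_implicit_ms - 60), 0.5 + 1e-12)

  # adding 100 Hz OPs to a band-limited composite and removing them again
  # barely moves b_amp
  t2 <- seq(-60, 350, by = 0.5)
  ab2 <- -150 * bump(t2, 40, 28) + 300 * bump(t2, 120, 40)
  ops <- 40 * ifelse(t2 >= 45, exp(-(t2 - 45) / 25) *
                       sin(2 * pi * 100 * (t2 - 45) / 1000), 0)
  trough2 <- measure_a_wave(erg_trace(t2, ab2), 0, c(0, 80))
  ref <- measure_b_wave(erg_trace(t2, ab2),
                        list(time_ms = trough2$a_implicit_ms,
                             value_uV = trough2$trough_uV))
  tr2 <- erg_trace(t2, ab2 + ops)
  sm2 <- subtract_ops(tr2, isolate_ops(tr2))
  m2 <- measure_b_wave(sm2, list(time_ms = trough2$a_implicit_ms,
                                 value_uV = trough2$trough_uV))
  expect_lt(abs(m2$b_amp_uV - ref$b_amp_uV), 5)
})

test_that("OP peaks of a damped sinusoid are evenly spaced and shift-equivariant", {
  p <- sim_params(noise_sd_uV = 0, a_amp_uV = 0, b_amp_uV = 0,
                  op_amp_uV = 40 / ergkit:::luminance_scale(-0.01, 0.05))
  tr <- synth_sweep(p, -0.01)
  op <- isolate_ops(tr)
  peaks <- detect_op_peaks(op, c(10, 100), min_prominence_uV = 5)
  expect_gte(nrow(peaks), 4)
  expect_true(all(diff(peaks$implicit_ms) > 0))
  spacing <- diff(peaks$implicit_ms[1:4])
  expect_true(all(abs(spacing - 10) <= 0.5 + 1e-12))

  # dense-grid argmax oracle for OP1 on the pure component
  t_dense <- seq(0, 100, by = 0.005)
  comp <- ergkit:::sim_components(p, -0.01, t_dense)
  op1_true <- t_dense[which.max(comp$op * (t_dense <= 30))]
  expect_lt(abs(peaks$implicit_ms[1] - op1_true), 1)

  # +5 ms onset delay moves every implicit time by +5 ms within one sample
  p2 <- p; p2$op_onset_ms <- p$op_onset_ms + 5
  peaks2 <- detect_op_peaks(isolate_ops(synth_sweep(p2, -0.01)),
                            c(10, 100), min_prominence_uV = 5)
  expect_true(all(abs(peaks2$implicit_ms[1:4] - peaks$implicit_ms[1:4] - 5)
                  <= 0.5 + 1e-12))
})

test_that("an empty window or flat trace yields no OP peaks, not an error", {
  t <- seq(-20, 100, by = 0.5)
  flat <- erg_trace(t, rep(0, length(t)))
  expect_equal(nrow(detect_op_peaks(flat, c(10, 60))), 0)
  expect_equal(nrow(detect_op_peaks(flat, c(500, 600))), 0)
})

test_that("eye selection follows the larger b-wave with right-eye tie-break", {
  mk <- function(eye, b) data.frame(animal_id = "m1", eye = eye,
                                    luminance_log = c(-1, 0),
                                    b_amp_uV = c(b / 2, b))
  both <- rbind(mk("left", 400), mk("right", 350))
  expect_equal(select_eye(both)$eye, "left")

  tied <- rbind(mk("left", 400), mk("right", 400))
  expect_equal(select_eye(tied)$eye, "right")

  expect_equal(select_eye(mk("left", 300))$eye, "left")

  nob <- rbind(mk("left", 400), mk("right", 350))
  nob$b_amp_uV[nob$luminance_log == 0] <- NA
  expect_error(select_eye(nob), class = "erg_no_bwave")
})

test_that("noiseless cohort extraction reproduces generator ground truth", {
  p <- quick_params(noise_sd_uV = 0)
  sim <- simulate_cohort(cohort_design(2), p, effect_spec(b_cv = 0, a_cv = 0,
                                                          op_delay_sd_ms = 0),
                         seed = 2, eye_cv = 0, eye_onset_sd_ms = 0)
  ft <- extract_features(sim$sweeps)
  key <- paste(ft$animal_id, ft$eye, ft$luminance_log)
  tkey <- paste(sim$truth$animal_id, sim$truth$eye, sim$truth$luminance_log)
  tr <- sim$truth[match(key, tkey), ]

  expect_true(all(abs(ft$b_amp_uV - tr$b_amp_uV) / tr$b_amp_uV < 0.02))
  ok <- !tr$a_fallback
  expect_true(all(abs(ft$a_amp_uV[ok] - tr$a_amp_uV[ok]) /
                    tr$a_amp_uV[ok] < 0.02))
  expect_equal(ft$a_fallback, tr$a_fallback)
  for (k in 1:4) {
    col <- paste0("op", k, "_implicit_ms")
    have <- !is.na(ft[[col]]) & !is.na(tr[[col]])
    expect_true(any(have))
    expect_true(all(abs(ft[[col]][have] - tr[[col]][have]) <= 1))
  }
})

test_that("trial counts follow the dim/bright repeat rule and row order is immaterial", {
  p <- quick_params()
  sim <- simulate_cohort(cohort_design(2), p, effect_spec(), seed = 4,
                         compute_truth = FALSE)
  ft <- extract_features(sim$sweeps)
  expect_true(all(ft$n_trials[ft$luminance_log == -1.2] == 10))
  expect_true(all(ft$n_trials[ft$luminance_log == -0.01] == 5))

  set.seed(99)
  perm <- sample(nrow(sim$sweeps))
  ft2 <- extract_features(sim$sweeps[perm, ])
  expect_equal(ft, ft2, ignore_attr = TRUE)
})

test_that("luminance response reports the saturating maximum a-wave", {
  p <- sim_params(noise_sd_uV = 0,
                  luminance_levels = c(-2.4, -1.2, -0.01))
  sim <- simulate_cohort(cohort_design(2, genotypes = "g",
                                       treatments = "t"),
                         p, effect_spec(genotypes = "g", treatments = "t",
                                        b_cv = 0, a_cv = 0,
                                        op_delay_sd_ms = 0),
                         seed = 6, eye_cv = 0, eye_onset_sd_ms = 0)
  ft <- select_eyes(extract_features(sim$sweeps))
  lr <- luminance_response(ft)

  # series sorted by luminance and monotone for a saturating generator
  for (d in split(lr$series, lr$series$animal_id)) {
    expect_equal(d$luminance_log, sort(d$luminance_log))
    expect_true(all(diff(d$b_amp_uV) > -1))
  }
  top <- sim$truth[sim$truth$luminance_log == -0.01, ]
  for (i in seq_len(nrow(lr$summary))) {
    tt <- top[top$animal_id == lr$summary$animal_id[i] &
                top$eye == ft$eye[match(lr$summary$animal_id[i],
                                        ft$animal_id)], ]
    expect_lt(abs(lr$summary$max_a_amp_uV[i] - tt$a_amp_uV) / tt$a_amp_uV,
              0.02)
  }

  single <- ft[ft$luminance_log == -0.01 & ft$animal_id == ft$animal_id[1], ]
  lr1 <- luminance_response(single)
  expect_equal(lr1$summary$max_a_amp_uV, single$a_amp_uV)
})
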