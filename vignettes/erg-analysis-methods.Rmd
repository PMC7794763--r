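---
title: "Scotopic ERG feature extraction and group statistics: methods"
author: "ergkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scotopic ERG feature extraction and group statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergkit)
```

## The measurement problem

A dark-adapted (scotopic) flash electroretinogram is the retina's mass
electrical response to a brief light flash, recorded at the cornea. Three
features carry most of the clinical and experimental signal:

* the **a-wave**, an initial negative deflection dominated by photoreceptor
  currents, measured from the pretrial baseline to the most negative point
  of the averaged trace;
* the **b-wave**, the subsequent positive deflection dominated by ON-bipolar
  cells, measured from the a-wave trough to the highest point of the trace
  *after* removal of the oscillatory potentials;
* the **oscillatory potentials (OPs)**, high-frequency wavelets riding on
  the b-wave's rising limb, attributed to inner-retinal (amacrine-driven)
  circuitry. Their **implicit times** (latency from stimulus onset to each
  peak, OP1–OP4) are a sensitive index of inner-retinal dysfunction in
  diabetic retinopathy models.

`ergkit` implements this measurement chain — trial averaging, baseline
estimation, OP isolation by a 25 Hz digital Butterworth high-pass,
a-/b-wave measurement, OP peak detection, per-animal eye selection — plus
the group-statistics layer used to compare genotype × treatment cohorts,
and a synthetic ERG generator with analytically known ground truth to
validate the whole chain.

## Extraction pipeline

For every (animal, eye, luminance) group, `extract_features()` performs:

1. **Averaging.** Repeated trials are averaged pointwise
   (`average_sweeps()`). Trial counts follow the acquisition convention of
   more repeats for dim flashes (10) than bright ones (5).
2. **Baseline.** The mean voltage over the pretrial window (all samples
   with `time_ms < 0` by default; configurable) defines the baseline.
3. **OP isolation.** A 4th-order Butterworth high-pass at 25 Hz is applied
   forward and backward (`isolate_ops()`). Zero-phase filtering is
   essential: OP implicit times are the headline latency metric, and a
   causal filter would bias them by its group delay. The effective
   magnitude response of the two passes is the squared single-pass
   response, $|H(f)|^2 = 1/(1 + (f_c/f)^{2n})$ with $f_c = 25$ Hz,
   $n = 4$. Before filtering, the trace mean is removed (a high-pass has
   zero DC gain, so this changes only edge transients and makes DC
   rejection exact); edges are padded by odd reflection over at least
   three filter impulse scales ($3 f_s / f_c$ samples).
4. **a-wave.** Measured on the *unfiltered* average: amplitude from the
   baseline down to the window minimum (default window 0–50 ms), implicit
   time at that minimum. Ties resolve to the earliest sample.
5. **OP subtraction and b-wave.** The high-pass (OP) trace is subtracted
   from the average; the b-wave amplitude runs from the a-trough value to
   the maximum of this smooth trace, its implicit time at that maximum.
   The a-on-raw / b-on-subtracted asymmetry is deliberate and follows the
   standard measurement convention.
6. **OP peaks.** Positive local maxima of the OP trace inside
   [a-implicit, b-implicit + 20 ms], filtered by topographic prominence
   (default 5 µV), time-ordered, first four retained. Fewer than four
   peaks yield missing values — never zeros — so downstream statistics can
   drop them.
7. **Eye selection.** Per animal, the eye with the larger b-wave amplitude
   at the maximal luminance is analysed (`select_eyes()`); ties break
   deterministically to the right eye.

### Numerical choices

* **OP detection band.** Peak *detection* runs on a copy of the OP trace
  additionally low-passed at 300 Hz (zero phase, configurable via
  `op_detect_lowpass_hz`). Broadband recording noise passes a 25 Hz
  high-pass essentially unattenuated, and its local maxima can exceed the
  5 µV prominence threshold, mislabelling OP3/OP4 by a full OP period.
  Restricting detection to the OP band (25–300 Hz, as band-pass OP
  protocols do) removes this failure mode while leaving peak times of
  100 Hz components untouched. The *subtraction* path remains the pure
  25 Hz high-pass, so `smooth + op` reconstructs the average exactly.
* **Dim-flash fallback.** When the measured a-wave amplitude falls below
  `min_a_amp_uV` (default 10 µV), the trough is undetectable and the
  b-wave is referenced to (stimulus onset, baseline) instead; the row is
  flagged `a_fallback`.
* **Edge trim.** The first and last 10 ms of a trace are excluded from
  peak searches to avoid filter edge transients.
* **Component separation is a band-limited property.** The identity
  "smooth trace ≈ OP-free composite" holds pointwise only when the OP-free
  part lies below the 25 Hz cutoff. A realistic 150 µV a-wave troughing at
  15 ms has appreciable energy above 25 Hz, and the high-pass legitimately
  captures ~45 µV of it at the trough. Amplitude accuracy for realistic
  morphology is therefore validated against generator ground truth
  (extraction matches to ~2% noiselessly), not by pointwise trace
  comparison.

## Synthetic generator and ground truth

`synth_sweep()` builds a sweep as

$$v(t) = -A_a\,g(t; t_a, k_a) + A_b\,g(t; t_b, k_b)
  + A_{op}\,e^{-(t-t_0)/\tau}\sin(2\pi f (t-t_0))\,[t \ge t_0]
  + \varepsilon(t) + \delta t$$

where $g$ is a unit-peak gamma kernel
$g(t; t_p, k) = (t/t_p)^{k-1} e^{(k-1)(1-t/t_p)}$, $\varepsilon$ is white
Gaussian noise and $\delta$ a linear drift. All response amplitudes scale
with flash strength through a saturating law $I/(I + k_{sat})$ on linear
luminance $I = 10^{\text{lum}}$. This is a minimal morphological model —
a negative lobe, a slower positive lobe, damped 100 Hz wavelets — with no
claim of biophysical fidelity (no Lamb–Pugh photoreceptor model).

Defaults describe a bright-flash rodent scotopic ERG: a 150 µV a-wave
troughing at 15 ms (shape 6), a 450 µV b-wave peaking at 60 ms (shape 8 —
late enough that the b-rise does not cancel the a-trough, as in real
recordings), 40 µV OPs at 100 Hz from 20 ms with 25 ms decay, 10 µV noise,
2 kHz sampling, and five flash strengths up to −0.01 log(cd·s/m²). The OP
frequency sits well above the 25 Hz analysis cutoff so the components are
cleanly separable, and the sampling rate is required to be ≥ 4× the OP
frequency.

`ground_truth()` computes the features the pipeline targets directly from
the noiseless composite by exhaustive search on a 10× oversampled grid —
no filtering is involved — using the same search windows and dim-flash
fallback rule. It is deterministic in the parameters and invariant to the
noise and drift settings, which makes it a valid oracle for parameter
recovery.

`simulate_cohort()` crosses genotype × treatment with per-cell effects:
multiplicative a-/b-amplitude factors and an additive OP delay.
Between-animal variability is lognormal for the amplitude factors
(CV 10% by default, keeping factors positive) and Gaussian for the delay
(SD 0.5 ms); each animal contributes two eyes with a small independent
jitter (3% amplitude CV, 0.2 ms onset SD), which gives `select_eyes()`
something real to choose between. OP amplitude scales with the b-factor,
reflecting their shared inner-retinal origin. All randomness streams from
one master seed through a counter scheme (one sub-seed per animal, per
eye, and per trial), so any single sweep is independently regenerable and
cohorts are byte-reproducible.

What the generator does **not** emulate: electrode drift nonlinearity,
mains interference, blink/movement artifacts, inter-trial adaptation, or
any biophysically derived luminance–response shape. Passing tests
therefore demonstrate correctness of the measurement chain under the
stated noise model, not robustness to every artifact of real recordings.

## Statistics

`two_way_anova()` is an ordinary fixed-effects factorial ANOVA. For
unbalanced designs the sum-of-squares type matters; the default is
**Type II** (each main effect adjusted for the other; interaction tested
from the full model), switchable to Types I and III. All types coincide
for balanced data. `summary_stats_anova()` runs the same analysis from
per-cell (mean, SEM, n) — the format of published tables. Because those
summaries are sufficient statistics for the fixed-effects decomposition,
the result is *exactly* the raw-data ANOVA of any sample realizing them;
internally such a sample is constructed by an affine transform of a
standardized sequence. Post-hoc comparisons use the residual mean square,
with Bonferroni adjustment $p_{adj} = \min(1, m\,p)$ over the declared
family; the default family for a 2×2 design is the four simple-effect
contrasts the study tables annotate (genotype within each diet, diet
within each genotype, $m = 4$). No correction is applied across luminance
levels: each luminance is a separate declared family, and the family size
is logged.

Degenerate zero-variance input returns SS = 0, F marked undefined
(`NA`), p = 1, with a warning — chosen over raising an error so that
simulation sweeps never crash. Effect sums of squares below numerical
round-off (relative 1e-12) report F = 0, p = 1.

The assay layer implements the standard closed forms: net luminescence
(firefly − Renilla, negative values flagged rather than clipped), fold
induction over the vehicle mean, relative qPCR expression by
$2^{-\Delta\Delta C_t}$ with technical replicates averaged per sample
first and amplification efficiency fixed at 2 (reference gene
configurable — GAPDH or L32, neither privileged), and least-squares
standard-curve quantification normalized to tissue mass, with
out-of-range readings extrapolated under a warning.

## Validation problem sizes

The shipped validation suite exercises: the analytic filter response at
5–200 Hz; exact decomposition conservation on 1000 random synthetic
traces; parameter recovery over 100 simulated 5-trial recordings at the
default noise level (median errors: ~3% a-wave, ~1% b-wave, ≤0.6 ms OP
implicit times; an injected +5 ms OP delay is recovered within one
sample); and the operating characteristics of the end-to-end cohort
analysis — 2×2 cohorts of 10 animals per cell at the top luminance, 200
runs with a 30% b-wave reduction confined to one cell for power, 1000
null runs for size. Cohort simulations for these operating-characteristic
sweeps use a single luminance and a 20/120 ms pre/post-trial window;
this is a problem-size choice for the sweeps, not a change to the
analysis path, which is identical to the full pipeline.

## Known limitations

* The OP detection rule (window, prominence, detection band) is not part
  of the source measurement convention and had to be fixed here; all
  three are configuration, and the defaults are documented above.
* Whether the pretrial baseline should use the whole pretrial record or a
  fixed sub-window is likewise configuration (default: whole record).
* `summary_stats_anova()` assumes the printed SEM is the within-cell
  standard error of the mean; summaries computed any other way (e.g.
  model-based SEs) would not reconstruct the raw ANOVA.
* Only pooled-error post-hoc t contrasts are provided; repeated-measures
  or mixed-effects structure across luminance levels is out of scope.
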