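---
title: "Spectral peaks and intrinsic neural timescales: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral peaks and intrinsic neural timescales: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`acwpeaks` quantifies two resting-state EEG markers of the state of
consciousness — the alpha/theta spectral peak and the autocorrelation
window (ACW) — and the statistical chain that relates them to a behavioral
consciousness score (CRS-R, 0–23). Clinical recordings from patients with
disorders of consciousness are confidential, so the package pairs the
analysis code with a synthetic cohort generator whose spectral and
temporal ground truth is known exactly; every claim the package makes is
testable against that ground truth or against brute-force oracles.

# The analysis model

## Pre-processing

The chain is order-fixed: downsample to 250 Hz (only when the input rate
is a multiple) → band-pass FIR 0.5–40 Hz (Hamming design) → bad-channel
detection and repair → common average reference → clip to 5 minutes.
Choices the verbal description of such pipelines leaves open are pinned as
follows:

* **Zero phase.** The FIR filter is applied as a delay-compensated
  linear-phase convolution (FFT-based). A causal application would shift
  the signal by half the filter order and bias the ACW; phase-free
  filtering avoids that. The filter order is about three periods of the
  low edge (≈ 1500 taps at 250 Hz), a standard transition-width heuristic;
  the pass-band is flat within ±1 dB over roughly [1, 36] Hz.
* **Flatline** means absolute successive differences below 1e-8 µV lasting
  more than 5 s — a numeric reading of "no activity".
* **Bursts** are samples beyond 5 robust standard deviations
  (1.4826 × MAD) of the channel's own median — the robust analogue of
  "SD = 5 relative to baseline".
* **Correlated channels** (|r| > 0.8) flag the later-indexed member of the
  pair, a deterministic tie-break.
* **Repair** replaces bad channels by the mean of the good channels.
  Spherical-spline interpolation needs 3-D electrode geometry that this
  package deliberately does not model; the substitute is isolated in
  `interpolate_bad()` and documented as such.
* A `drift` reason code exists but is never populated: no quantitative
  drift criterion is defined, and we chose not to invent one.

## Spectra and peak measures

Power spectral densities use Welch's method: 3 s segments, 50 % overlap,
Hamming taper, density (per-Hz) normalization — so the integral of the
PSD approximates the variance, which the tests assert (Parseval). Each
segment is linearly detrended before tapering so that residual DC cannot
leak into the 0.5 Hz bin; the trailing partial segment is dropped. Linear
power is averaged across the three electrodes of each region of interest
*first*, and the log10 is taken afterwards; all peak analysis operates on
the log10 values restricted to 0.5–40 Hz.

The peak machinery is implemented from first principles because it *is*
the contribution:

* a **local maximum** is a sample strictly above its neighbours; plateaus
  count once, at their first index; endpoints never qualify;
* **prominence** traces a horizontal line from the peak left and right
  until the signal end or the slope of a higher peak, takes the minimum of
  each traced segment, and subtracts the greater minimum from the peak
  height;
* **width** is the distance between the two crossings of the descending
  slopes with the reference line at half prominence, linearly interpolated
  between grid points. If a slope leaves the grid before crossing (possible
  only when a caller supplies an externally derived prominence), the
  crossing clamps to the grid edge and a boundary flag is set;
* detection keeps maxima with prominence ≥ 0.1 (log10-power units) and
  enforces a minimal mutual distance of 0.4 Hz, keeping the more prominent
  of any close pair, ties toward lower frequency;
* the most prominent surviving peak with frequency in 3–13 Hz is labeled
  **alpha** when its frequency is ≥ 7.5 Hz and **theta** below; 7.5 Hz
  itself is assigned to alpha, making the two bands disjoint
  ([3, 7.5) and [7.5, 13]).

Both prominence and width are checked, on a thousand random sequences,
against a brute-force oracle that literally walks these definitions.

**Power ratio.** The ratio of peak power to maximum power is computed on
the *linear* scale, `10^(power − max_power)`, which is guaranteed to lie
in (0, 1] and matches the plausible published range (≈ 0.66–0.82). A
ratio of two negative log10 values can exceed 1 and flips its ordering;
the log variant remains available via `spectral_measures(..., ratio =
"log")` for comparison, but linear is the default and the documented
interpretation.

## Timescales

The autocorrelation function is the biased (1/n) estimator of the
mean-removed series, computed by FFT; bias keeps the values in [−1, 1]
and the sequence positive semidefinite. ACW-50, ACW-e⁻¹ and ACW-0 are the
first lags at which the ACF *drops to or below* 0.5, e⁻¹ and 0 — decaying
ACFs approach the threshold from above, and "reaches" is read as the
first crossing, consistent with ACW-0 as the first zero crossing. The
maximum lag defaults to 20 s, far beyond any EEG ACW of interest (medians
in patient data are ~0.06–0.08 s) while bounding compute; a threshold
never reached within the lag range yields a censored value, which ROI
averaging excludes with a warning and group statistics drop with a logged
count. The ACW is computed on the full pre-processed 5-minute trace — the
band-pass's effect on the ACF is inherited, not corrected — and, like the
spectra, averaged across the three electrodes per ROI.

## Inference

* Two-group contrasts gate on Shapiro–Wilk at α = 0.05 per sample (the
  gate's α is not prescribed anywhere; 0.05 is the conventional choice):
  both normal → independent equal-variance t-test, otherwise
  Mann–Whitney U. All tests are two-sided. A constant sample is treated
  as failing the gate, since Shapiro–Wilk is undefined for it.
* Correlations gate the same way between Pearson and Spearman, except
  that any correlation involving the ordinal CRS-R is forced to Spearman.
* Benjamini–Hochberg correction is applied per (ROI × analysis block)
  family, and the family membership is recorded in the outputs.
* The chi-square on peak-occurrence tables is Pearson's, without
  continuity correction.
* Quantile splits are rank-based with stable ties (sort by value, then
  id) and the remainder assigned to the lowest groups — 95 subjects split
  3-ways as 32/32/31.
* Mediation is ordinary-least-squares product-of-coefficients after
  standardization, with a case-resampling percentile bootstrap (default
  5000 resamples, re-standardized within each resample) for the CI and a
  two-sided bootstrap p-value. A structural-equation treatment with an
  ordinal outcome link was considered and rejected: the score enters as
  standardized numeric, its ordinality honored in the correlation gating
  instead. This is the simplest defensible estimator consistent with
  "bootstrap after standard scaling", and it is fully self-contained and
  reproducible.

## Classification

One-vs-one coding: N(N−1)/2 binary maximum-margin classifiers
(linear kernel, unit box constraint — the published description names
neither, and "the model optimized the hyperparameters" is not
operationalizable, so the simplest classical choice is pinned and
exposed as arguments), majority-vote decoding with ties broken by summed
decision values. Folds are stratified (the minority classes are small)
and features are standardized *inside* each training fold only — a
leakage test asserts that corrupting a test row cannot change the
predictions of its fold peers. Accuracy and the per-class metrics are
averaged across folds; the confusion matrix is pooled; AUC is the macro
average of one-vs-rest rank AUCs of the pooled decision scores, one
defensible reading of an otherwise undefined multiclass AUC.

# The synthetic cohort

## What it emulates

Each channel is an independent realization of a phenotype: an AR(1)
backbone with lag-one coefficient `exp(-1/(fs·τ))` carrying 70 % of the
background variance (this sets the intrinsic timescale τ), aperiodic
1/f^e noise carrying 30 % (spectral shaping of white noise — the
frequency-domain amplitude is scaled by f^(−e/2), giving the exact
expected spectrum in O(n log n)), plus an optional band-limited
oscillation: white noise shaped by a Gaussian spectral envelope, which
produces a peak of realistic width (a pure sinusoid would make the width
measure degenerate). Innovation variances are set so the background has
unit variance before mixing, making oscillation amplitudes interpretable
as signal-to-background RMS ratios; the sum is scaled to a 20 µV RMS.

Stock phenotypes follow the qualitative clinical picture: `control`
(alpha bump at 10 Hz, amplitude 1.2, τ = 0.03 s, exponent 1), `doc_theta`
(5 Hz bump, amplitude 0.8, τ = 0.06 s, exponent 1.5), `doc_flat` (no
bump, τ = 0.09 s, exponent 2). No absolute published amplitudes exist to
calibrate against, so amplitudes were chosen once to reproduce the
qualitative detection rates (controls ≳ 90 % alpha peaks, flat patients
≲ 10 % spurious peaks through the full pipeline) and are not tuned
further.

At the cohort level a latent mediation chain with known paths (a, b) ties
everything together: a peak-power factor x ~ N(0,1), a timescale factor
m = a·x + σε, and a consciousness latent y = b·m + σε discretized to a
0–23 integer score by rounding and clipping (the affine map 8 + 3.5·y
keeps clipping rare, preserving rank structure for Spearman). Higher m
maps to *shorter* channel timescales and higher x to stronger
oscillations, so the generated EEG reproduces the published directions:
peaked patients have shorter ACWs, longer-ACW patients have lower scores,
and the indirect effect a·b is recoverable from the latent ground truth.
Patients with x > 1.1 keep an alpha-range (9 Hz) bump, x in (0.1, 1.1]
get the theta bump, the rest are flat — approximating the published
occurrence proportions (~10 % alpha, ~25 % theta, ~65 % none); 12 % of
controls are generated as low-voltage (no alpha bump), matching the known
prevalence of that healthy phenotype. MCS labels go to the higher-scoring
half of patients by rank, so MCS/UWS differ in score but overlap heavily
in EEG features — which is exactly why the three-class task is harder
than the two-class one, as in the published classification experiments.

## What it does not emulate

No ocular/muscular/cardiac artifacts (hence no ICA stage), no volume
conduction or electrode geometry (channels are independent realizations;
the spherical-spline substitute is untestable against real geometry), no
eyes-open/closed state, no etiology effects. Passing tests therefore
demonstrate the correctness and internal consistency of the measures and
inference chain — not that real patient data would yield the published
effect sizes.

# Numerical choices and degenerate inputs

* Sample k of a recording corresponds to time k/fs with 0-based k;
  autocorrelation lags are exact multiples of 1/fs.
* Zero-power spectral bins map to −∞ log power and are rejected by peak
  analysis (the analysis band must be restricted first).
* Degenerate contrasts or correlations (constant samples — e.g. every
  control peak landing on the same 1/3 Hz grid frequency) are skipped and
  recorded as NA rather than fabricating a p-value.
* All generators are pure functions of (parameters, seed); the pipeline
  derives stage seeds deterministically from one master seed, and a fixed
  configuration reproduces byte-identical CSV outputs (numbers written at
  12 significant digits).

# Problem sizes used by the test and acceptance suites

Module tests run on deliberately small inputs (tens of seconds of signal,
cohorts of ~30) chosen so each property is decided well away from its
threshold. The acceptance suite runs the full study conditions where they
matter: 5-minute recordings at 250 Hz, the 25/47/48 cohort, 20 seeds per
recovery condition, 1000 random sequences for the oracle equivalence, and
5000 bootstrap resamples for mediation.

# Known limitations

* The interpolation substitute changes bad channels' spectra more than a
  geometry-aware method would; with the default synthetic cohort bad
  channels are rare, so the effect is negligible in practice. A further
  consequence of the mean substitute is that a repaired channel equals
  the common average exactly, so re-referencing zeroes it; such channels
  carry no independent signal and are excluded from the ROI averages by
  `analyze_recording()`.
* The ACW inherits the band-pass: the 40 Hz low-pass smooths the very
  shortest timescales upward, visible for τ ≲ 0.02 s. Timescale-recovery
  guarantees are therefore stated for the unfiltered AR(1) oracle.
* `width` at the band edge depends on the boundary-clamp policy; flagged
  rows should be treated with care in downstream statistics.
* The classification defaults (linear kernel, C = 1) are a floor, not a
  tuned ceiling; published accuracies on real data are not reproducible
  from synthetic cohorts and are not targeted.
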