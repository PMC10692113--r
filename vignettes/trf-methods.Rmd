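---
title: "Forward TRF analysis of sung speech: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward TRF analysis of sung speech: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question and the model

`rhymetrf` studies how strongly continuous (sung) speech is encoded in
low-frequency EEG, and in particular whether *phonetic feature categories*
are encoded beyond what the sound's acoustics explain — the signature of
acoustically invariant phonetic processing. The workhorse is the forward
multivariate temporal response function (mTRF): for channel $c$,

$$\hat{y}_c(t) = b_c + \sum_{f} \sum_{\tau = \tau_{\min}}^{\tau_{\max}}
  w_{f,\tau,c}\, x_f(t - \tau),$$

a lagged linear regression from stimulus features $x_f$ onto the EEG.
Weights are estimated by penalised least squares (Tikhonov/ridge),
$w = (X^\top X + \lambda M)^{-1} X^\top y$, with an unpenalised intercept
and either an identity penalty $M$ (per-coefficient ridge, the default) or
a banded second-difference penalty over each feature's lags (a smoothness
prior; both are common for TRFs).

Four stimulus streams serve as regressors:

* **S** — an 8-band amplitude-envelope spectrogram. Band edges between
  250 Hz and 8 kHz are spaced uniformly in cochlear position under the
  Greenwood map $F(x) = A(10^{ax} - k)$ with the standard human constants
  $A = 165.4$, $a = 2.1$, $k = 0.88$. Each band is extracted with a
  4th-order zero-phase Butterworth band-pass, its envelope is the
  magnitude of the analytic signal, and envelopes are anti-alias filtered
  and resampled to the analysis rate. Amplitudes stay linear (no
  compression); a practitioner preferring power-law compression can apply
  it to `S` before model fitting.
* **D** — the half-wave-rectified first difference of the broadband
  envelope (the row-sum of S), an acoustic-onset nuisance regressor. D is
  computed after resampling, and its first sample is defined as 0.
* **F** — a binary 14-column matrix of articulatory phonetic features
  (voicing, manner, place: voiced/unvoiced consonant, plosive, fricative,
  nasal, strident, labial, coronal, dorsal, anterior, front, back, high,
  low). Each phoneme paints its feature vector as a unit rectangular pulse
  from onset to offset; overlaps combine by logical OR. The shipped
  phoneme table (`inst/extdata/phoneme_features.tsv`) is an ARPAbet-like
  British English inventory reconstructed from standard
  articulatory-phonetics conventions; it is a plain TSV and fully
  replaceable via `feature_inventory()`.
* **V** — mean absolute frame-to-frame luminance change of the stimulus
  video, a visual-motion nuisance regressor.

Model scores are *EEG prediction correlations*: Pearson's $r$ between the
cross-validated prediction of each channel and a **ground-truth EEG
trace** — the grand average over all channels and all participants of a
group, band-filtered to the band of interest. Correlating every
participant's prediction against one shared trace removes
between-participant SNR differences from the score. This construction
relies on mastoid referencing: under a global average reference the
across-channel mean would be identically zero.

The phonetic encoding statistic is the **FS−S prediction gain**: the
across-channel mean $r$ of the acoustic-phonetic model {S, D, V, F} minus
that of the acoustic-only model {S, D, V}, per participant and band. A
positive gain indicates variance explained by phonetic categories beyond
acoustics.

## Estimation details

* **Lag window.** −100 to 500 ms at the analysis rate; endpoints are
  converted to samples by rounding half away from zero and are inclusive
  (31 lags at 50 Hz). Negative (acausal) lags absorb regression edge
  artefacts so that positive lags stay interpretable.
* **Cross-validation.** Leave-one-trial-out. Within each training fold,
  $\lambda$ is tuned by an inner leave-one-out search over a logarithmic
  grid (default $10^{-2} \ldots 10^{6}$), maximising the mean prediction
  correlation over inner folds and channels; ties resolve toward the
  smaller $\lambda$. With a single training trial (two-trial datasets) the
  inner search validates on the trial's second half. One $\lambda$ is
  shared across channels per participant/model/band.
* **Scaling.** Feature streams are scaled to unit variance using
  training-fold statistics only (a leakage guard); the intercept absorbs
  means. Prediction correlations are invariant to affine rescaling of the
  EEG, so the response is not rescaled.
* **Aggregation.** Per-channel $r$ is averaged across folds, then across
  channels — including unresponsive channels, which makes the scores
  conservative.
* **Numerics.** Normal equations are accumulated per trial (Gram
  matrices), so every training fold is a sum of precomputed blocks; solves
  use Cholesky factorisation. A singular system at $\lambda = 0$ raises an
  error advising $\lambda > 0$. The full chain is deterministic: identical
  inputs and seeds give byte-identical outputs.

## Preprocessing chain

Facial electrodes are excluded first (they are not part of the infant-net
montage), then: 8 Hz low-pass, 0.1 Hz high-pass (order-2 zero-phase
Butterworth, applied forward and backward), downsampling to 50 Hz
(zero-phase anti-alias filter plus exact-time interpolation, so no group
delay), an artifact-cleaning hook (pass-through by default; an external
cleaner such as an artifact-subspace method can be plugged in), bad-channel
detection and interpolation, mastoid re-referencing (mastoids then
dropped), and averaging of repeated presentations. On a 64-channel net
this yields the 58 analysis channels. Band-specific filtering (low-delta
0.1–1, delta 1–4, theta 4–8 Hz) is applied downstream, to analysis copies.

Bad channels are flagged when the z-score of their excess kurtosis or of
their log-variance (against the across-channel distribution) exceeds 3;
these two statistics stand in for the "probability and kurtosis" criteria
of standard EEG toolboxes. Flagged channels are rebuilt by
inverse-distance-weighted averaging of the 4 nearest clean channels on the
3-D montage — a simpler stand-in for spherical-spline interpolation, and a
documented limitation. Statistics are computed per session. If more than
half the montage is flagged the chain aborts rather than interpolate its
way out.

## The synthetic longitudinal cohort

Because the source infant EEG is confidential, every stage is validated on
a fully synthetic cohort with known ground truth:

* **Stimuli.** Phoneme sequences tile each trial with log-normal
  durations (mean rate 5 phonemes/s). F is produced by the same
  `phonetic_feature_matrix()` code path the real-data branch uses. S mixes
  a phoneme-template-driven component (each phoneme has a smooth positive
  8-band spectral template, modulated by a random prosodic envelope) with
  independent smooth noise; the mixing weight (0.35 by default) sets the
  acoustic S/F confound. Real nursery-rhyme spectrograms are dominated by
  prosody and melody rather than phoneme identity, which is why the
  phoneme-driven share is kept below half; the confound is deliberately ON
  so that the FS−S null is a real test of acoustic invariance, not a
  triviality. D derives from S; V is smooth independent noise.
* **Forward model.** Each scalp channel is the lagged convolution of S
  and F with channel-specific kernels spanning 0–400 ms — exactly the
  model the TRF estimator assumes — plus 1/f-spectrum noise (10% white)
  scaled relative to the clean signal SD (default ratio 1). Temporal
  kernels are two-Gaussian-bump curves with amplitudes bounded away from
  zero; channel profiles share a smooth common spatial map with modest
  per-feature deviations, giving the consistent-polarity, mutually similar
  topographies characteristic of auditory far-field responses under a
  mastoid reference. (With independent zero-mean profiles per feature the
  grand-average-trace methodology itself becomes incoherent, so this is a
  modelling requirement, not a convenience.) Mastoid channels carry an
  attenuated copy of the mean scalp signal plus noise; facial channels are
  noise.
* **Phonetic gain.** The phonetic kernels are RMS-calibrated against the
  acoustic drive on a reference stimulus, so a session gain of $g$ means
  "phonetic contribution with $g$ times the RMS of the acoustic
  contribution". The default longitudinal structure uses gains (0, 0.5, 1)
  across sessions at 4, 7 and 11 months, 18 trials of 30 s per session at
  50 Hz, a 64-channel montage, 3 repetitions per trial and a 20% chance of
  losing one repetition (infants often complete 2 of 3).
* **Seeding.** All randomness derives from one master seed through a
  string-keyed hash (`derive_seed()`); no global RNG state is consumed.
  The hidden kernels and gains (`SimTruth`) are returned separately and
  never serialised with the dataset.

What the generator does **not** emulate: realistic phonotactics or
prosodic hierarchy, head-model (leadfield) geometry, non-stationary
artefacts, or eye movements. Passing tests therefore demonstrate that the
estimation and inference machinery is correct under the assumed forward
model — not that the pipeline is robust to every property of real infant
EEG.

## Problem sizes used by the test and analysis runs

Estimating a 24-feature × 31-lag model per participant, model, band and
fold is the dominant cost, so the packaged experiments run at reduced
problem sizes chosen once: the cohort analyses use 20 participants × 3
sessions, 5 trials × 12 s at 25 Hz on a 40-channel montage with a 3-point
$\lambda$ grid ($10^0, 10^{2.5}, 10^5$); the null-calibration cohorts use
n = 15 with 3 trials × 8 s; kernel recovery runs at the full 18 trials ×
30 s, 50 Hz. The kernel-recovery fit low-passes both the EEG and the
regressors at 8 Hz with the same zero-phase filter: linear filters commute
with convolution, so the band-limited regression remains exactly specified
while out-of-band noise is removed.

## Finite-sample behaviour of the FS−S gain

Two properties of the gain statistic deserve explicit documentation.

First, adding the 14 × L phonetic columns to the design lets the model fit
noise; at test time that fitted noise dilutes the prediction correlation.
The resulting **negative bias** of the gain under the null scales roughly
as (extra parameters)/(training samples). At the study-scale data volume
(≈36 training rows per phonetic parameter) it is negligible against the
between-participant spread; at the reduced volumes used in desk-scale
simulation (2–6 rows per parameter) it dominates, and the one-sample
Wilcoxon on null-cohort gains rejects far above its nominal level. The
`analysis/05_null_calibration.R` driver quantifies this, and the
corresponding acceptance check is expected to fail at these problem sizes
— deliberately left in place as an honest negative result. Session
*contrasts* (the age effect) are largely unaffected, because the bias is
common to all sessions of a participant; the age-effect recovery
experiment demonstrates this. A related caveat: roughly one synthetic
cohort in ten draws phonetic kernels whose delta-band, channel-averaged
projection adds little beyond what the acoustic model captures, so that
cohort's measured gains are nearly flat across sessions even though the
generating gains are ordered. The incidence of such "flat" cohorts is a
property of the kernel draw, not of data volume, which is why the
strict-ordering check on session means holds in about three quarters of
scaled replicates rather than all of them.

Second, band-filtering the EEG but not the regressors smears the effective
kernels beyond the lag window (a zero-phase band filter has acausal,
long-tailed impulse response); the truncated tails act as structured
unexplained variance, which slightly inflates the same bias. This is
inherent to estimating band-limited TRFs with a finite lag window and is
shared by the standard methodology; filtering the regressors to a narrow
band instead is not an option, as it collapses the design's rank.

## Statistical battery

Group comparisons across sessions use a screened flow: Shapiro-Wilk
normality per condition at α = .05 (any failure → Friedman test with
Kendall's $W = \chi^2 / (n(k-1))$ as effect size); otherwise Mauchly's
sphericity test (failure → repeated-measures ANOVA with
Greenhouse-Geisser-corrected degrees of freedom, $\varepsilon$ computed
from the sample covariance of conditions and bounded in $[1/(k-1), 1]$);
otherwise the uncorrected rmANOVA. Effect size for the rmANOVA is partial
$\eta^2 = SS_{cond}/(SS_{cond}+SS_{err})$. Post hoc tests are two-tailed
Wilcoxon signed-rank tests (exact by enumeration-equivalent computation up
to n = 15 without ties, normal approximation with continuity correction
otherwise; zeros dropped). When post hoc comparisons span several models
and bands, all their p-values are Benjamini-Hochberg-corrected as a single
family. Topographic similarity to a reference group is assessed by a
bootstrap: resample `group_size` participants (default 17) with
replacement, average their channel-wise $r$ topographies, correlate with
the reference map; 100 iterations, seed-reproducible. A first-word ERP
SNR control (post/pre power ratio around the first word's onset, default
0.5 s windows) guards against group SNR confounds.

## Known limitations

* Inverse-distance bad-channel interpolation is cruder than spherical
  splines; heavily corrupted montages should be cleaned upstream.
* The artifact-subspace-reconstruction step of the original chain is a
  pass-through hook, not a reimplementation.
* EDF ingestion is not implemented; recordings arrive through the
  package's plain-text directory containers (or are simulated).
* The FS−S gain carries the finite-sample bias described above; absolute
  gains from small datasets should be read against a matched-size null,
  e.g. via `gain_cohort_experiment(session_gains = 0, ...)`.
* The phoneme inventory is a reconstruction; users with a study-specific
  inventory should supply their own table.
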