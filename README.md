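# rhymetrf

Forward temporal-response-function (TRF) analysis of how continuous sung
speech — nursery rhymes — is encoded in low-frequency EEG, built for
developmental neuroscientists studying the emergence of phonetic category
encoding across infancy and for anyone validating TRF methodology on
simulated cohorts.

The scientific core is a multivariate lagged ridge regression from
stimulus features to EEG,

    y_c(t) = b_c + sum_f sum_tau w(f, tau, c) x_f(t - tau) + e(t),

estimated with Tikhonov regularisation over a −100…500 ms lag window and
nested leave-one-trial-out cross-validation. Stimulus features are an
8-band Greenwood-spaced auditory spectrogram (S), the half-wave-rectified
broadband envelope derivative (D), a binary matrix of 14 articulatory
phonetic features (F), and a visual-motion regressor (V). Model quality is
the Pearson correlation between predicted EEG and a *ground-truth* trace
(the grand average across all channels and participants of a group,
band-filtered to the low-delta/delta/theta band of interest). Acoustically
invariant phonetic encoding is quantified by the **FS−S prediction gain**

    gain = r({S,D,V,F}) − r({S,D,V}),

the improvement in cross-validated prediction correlation from adding
phonetic features to an acoustic-only model. The package also ships the
full repeated-measures statistical battery (Shapiro/Mauchly screening,
rmANOVA with Greenhouse–Geisser correction, Friedman with Kendall's W,
exact Wilcoxon signed-rank, joint BH-FDR, topography bootstrap, first-word
ERP SNR control) and a synthetic longitudinal EEG cohort generator with
known convolution kernels, so the entire pipeline is testable end to end
without any confidential recordings.

## Worked example

Simulate a small longitudinal cohort whose phonetic kernel gain grows
across sessions (0, 0.5, 1 at "4mo", "7mo", "11mo"), then run the full
analysis — preprocessing, per-band ground-truth traces, single-feature
TRFs, the conditional FS−S gain stage, and the statistical battery:

```r
library(rhymetrf)

cfg <- default_run_config(seed = 42, simulate = list(
  n_participants = 20, sessions = c("4mo", "7mo", "11mo"),
  session_gains = c(0, 0.5, 1), n_trials = 5, trial_duration = 12,
  fs = 25, n_channels = 40, n_repetitions = 3, dropout_prob = 0.2))
cfg$bands       <- list(delta = c(1, 4), theta = c(4, 8))
cfg$lambda_grid <- 10^c(0, 2.5, 5)
cfg$preprocess  <- list(lowpass = NULL, highpass = NULL, fs_out = 25,
                        order = 2, interpolate = FALSE)

bundle <- run_full_analysis(cfg)
aggregate(gain ~ band + session, bundle$gains, mean)
```

On this cohort the delta band (but not theta) shows a significant age
effect for the phonetic model, so only delta carries the gain analysis,
and the session-mean gains rise with age:

```
   band session        gain
1 delta    11mo  0.04393686
2 delta     4mo -0.02417163
3 delta     7mo -0.00493624
```

with `age_effect_gain_delta: F(2, 38) = 16.2, p = 8.3e-06` and
FDR-corrected Wilcoxon contrasts `11mo > 4mo (p = 0.0009)` and
`11mo > 7mo (p = 0.010)`. Positive gains emerge only in the session whose
generating phonetic gain is largest — the pattern the method is designed
to detect. (Small negative gains in the no-phonetics session reflect the
finite-sample bias of cross-validated gains at reduced data volumes; the
methods vignette and `analysis/05_null_calibration.R` quantify it.)

The numbered scripts under `analysis/` run this study as a sequence —
`01_simulate_cohort.R`, `02_single_feature_trf.R`, `03_prediction_gain.R`,
`04_kernel_recovery.R`, `05_null_calibration.R` — writing tables under
`results/`. Kernel recovery at the study-scale data volume (18 trials ×
30 s, noise SD = signal SD) correlates fitted TRF weights with the hidden
generator kernels at `r = 0.98` (spectrogram) and `r = 0.93` (phonetic
features).

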