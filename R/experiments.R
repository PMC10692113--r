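# Self-contained validation experiments built from the package's own
# operations: kernel recovery for a single simulated participant, and
# cohort-level FS-S gain computation. Shared by the test suite, the
# acceptance script and the analysis drivers.

#' Kernel recovery for one simulated participant
#'
#' Simulates a participant with known acoustic and phonetic kernels
#' (forward convolution plus 1/f noise), fits a single acoustic-phonetic
#' TRF on the matched-filtered data (both EEG and regressors low-passed at
#' 8 Hz with the same zero-phase filter, which keeps the band-limited
#' regression exactly specified), and correlates the fitted weight slices
#' with the generating kernels.
#'
#' @param seed master seed.
#' @param n_trials,duration,fs trial structure (defaults: 18 trials of
#'   30 s at 50 Hz).
#' @param noise_sd noise SD relative to the clean signal SD.
#' @param n_channels scalp channels simulated.
#' @param lambda ridge parameter for the demonstration fit.
#' @param gain phonetic kernel gain.
#' @return list with `r_S`, `r_F` (pooled weight/kernel correlations) and
#'   the fitted `trf_model`.
#' @export
kernel_recovery_experiment <- function(seed, n_trials = 18, duration = 30,
                                       fs = 50, noise_sd = 1,
                                       n_channels = 8, lambda = 3000,
                                       gain = 1) {
  inv <- default_feature_inventory()
  tm <- make_spectral_templates(inv, 8, derive_seed(seed, "templates"))
  lags <- seq.int(0L, round_half_away(0.4 * fs))
  K_S <- make_kernels(8, lags, n_channels, derive_seed(seed, "K_S"))
  K_F <- make_kernels(14, lags, n_channels, derive_seed(seed, "K_F"))
  truth <- list(K_S = K_S, K_F = K_F, kernel_lags = lags)
  # RMS-calibrate the phonetic kernels on a reference stimulus, matching
  # the cohort generator's convention for the gain parameter
  al0 <- generate_phoneme_sequence(inv, 5, duration, derive_seed(seed, "calib"))
  ft0 <- generate_stimulus_features(al0, inv, tm, fs, duration, 0.35,
                                    derive_seed(seed, "calibstim"))
  kw <- structure(list(lags = lags), class = "lag_window")
  pS <- lag_design_matrix(ft0$S, kw) %*%
    matrix(aperm(K_S, c(2, 1, 3)), ncol = n_channels)
  pF <- lag_design_matrix(ft0$F, kw) %*%
    matrix(aperm(K_F, c(2, 1, 3)), ncol = n_channels)
  if (stats::sd(as.numeric(pF)) > 0)
    truth$K_F <- K_F * stats::sd(as.numeric(pS)) / stats::sd(as.numeric(pF))

  lp <- function(m) apply(m, 2, function(v)
    zero_phase_bandpass(v, high = min(8, fs / 2 * 0.9), order = 2, fs = fs))
  feats <- vector("list", n_trials)
  eeg <- vector("list", n_trials)
  for (ti in seq_len(n_trials)) {
    al <- generate_phoneme_sequence(inv, 5, duration,
                                    derive_seed(seed, paste0("seq", ti)))
    ft <- generate_stimulus_features(al, inv, tm, fs, duration, 0.35,
                                     derive_seed(seed, paste0("stim", ti)),
                                     trial_id = ti)
    e <- simulate_eeg_from_kernels(ft, truth, g = gain, noise_sd = noise_sd,
                                   seed = derive_seed(seed,
                                                      paste0("noise", ti)))
    feats[[ti]] <- lp(model_matrix_from_features(ft, c("S", "F")))
    eeg[[ti]] <- zero_phase_bandpass(e$data, high = min(8, fs / 2 * 0.9),
                                     order = 2, fs = fs)
  }
  w <- lag_window(-0.1, 0.5, fs)
  fit <- trf_fit(feats, eeg, w, lambda = lambda)
  idx <- match(lags, w$lags)
  list(r_S = stats::cor(as.numeric(fit$weights[1:8, idx, ]),
                        as.numeric(truth$K_S)),
       r_F = stats::cor(as.numeric(fit$weights[9:22, idx, ]),
                        as.numeric(truth$K_F)),
       fit = fit)
}

#' Per-participant FS-S gains for a simulated cohort
#'
#' Simulates a longitudinal cohort and runs the gain stage of the pipeline
#' (acoustic-phonetic vs acoustic-only cross-validated TRFs against the
#' cohort ground-truth trace) in one frequency band, returning the
#' participants x sessions gain matrix.
#'
#' @param seed master seed.
#' @param session_gains phonetic gain per session.
#' @param n_participants cohort size.
#' @param n_trials,trial_duration,fs,n_channels,n_repetitions,dropout_prob
#'   scaled cohort structure (see [sim_config()]).
#' @param lambda_grid candidate regularisation values.
#' @param band analysis band in Hz (default delta, 1-4).
#' @return participants x sessions numeric matrix of gains.
#' @export
gain_cohort_experiment <- function(seed, session_gains = c(0, 0.5, 1),
                                   n_participants = 20, n_trials = 5,
                                   trial_duration = 12, fs = 25,
                                   n_channels = 40, n_repetitions = 3,
                                   dropout_prob = 0.2,
                                   lambda_grid = 10^c(0, 2.5, 5),
                                   band = c(1, 4)) {
  cfg <- default_run_config(seed, simulate = list(
    n_participants = n_participants,
    sessions = paste0("ses", seq_along(session_gains)),
    session_gains = session_gains, n_trials = n_trials,
    trial_duration = trial_duration, fs = fs, n_channels = n_channels,
    noise_sd = 1, n_repetitions = n_repetitions,
    dropout_prob = dropout_prob))
  cfg$bands <- list(band = band)
  cfg$models_single <- list()
  cfg$gain_band_selection <- FALSE
  cfg$lambda_grid <- lambda_grid
  cfg$snr <- NULL
  # the band filter subsumes the broadband conditioning at these rates
  cfg$preprocess <- list(lowpass = NULL, highpass = NULL, fs_out = fs,
                         order = 2, interpolate = FALSE)
  bundle <- run_full_analysis(cfg)
  g <- bundle$gains
  sessions <- unique(g$session)
  out <- vapply(sessions, function(s) g$gain[g$session == s],
                numeric(n_participants))
  dimnames(out) <- list(unique(g$participant), sessions)
  out
}
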