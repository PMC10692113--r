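# Synthetic stimuli and longitudinal EEG cohorts with known ground truth.
# The generator emulates the study design: 18 nursery-rhyme trials per
# session, correlated S/F stimulus streams, channel-specific convolution
# kernels, 1/f noise, repeated presentations with infant-style dropout, and
# a 3-session longitudinal structure in which the phonetic kernel gain
# increases with age while the acoustic kernels stay fixed.

#' Configuration for the synthetic longitudinal cohort
#'
#' Defaults mirror the emulated study: 3 sessions (4, 7, 11 months) with
#' phonetic kernel gains (0, 0.5, 1), 18 trials per session, a 64-channel
#' montage (58 scalp + 2 mastoid + 4 facial), noise SD equal to the clean
#' signal SD, and an acoustic confound that makes the spectrogram partially
#' predictive of the phonetic features.
#'
#' @param n_participants cohort size.
#' @param sessions session labels.
#' @param session_gains phonetic kernel gain per session (>= 0).
#' @param n_trials trials (nursery rhymes) per session.
#' @param trial_duration trial length in seconds.
#' @param fs analysis sampling rate in Hz.
#' @param n_channels total channels (4 facial + 2 mastoids + scalp).
#' @param noise_sd noise SD relative to the clean signal SD.
#' @param confound S/F acoustic-confound strength in `[0, 1]`.
#' @param kernel_jitter SD of participant-specific kernel perturbations,
#'   relative to the cohort kernel scale.
#' @param kernel_span TRF kernel support in seconds (from lag 0).
#' @param phoneme_rate mean phonemes per second in generated sequences.
#' @param n_repetitions presentations per trial before averaging.
#' @param dropout_prob probability that a trial has one repetition fewer
#'   (infants often complete 2 of 3).
#' @param white_fraction fraction of noise power that is white (the rest
#'   has a 1/f spectrum).
#' @param seed master seed; every random stream is derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_participants = 50,
                       sessions = c("4mo", "7mo", "11mo"),
                       session_gains = c(0, 0.5, 1),
                       n_trials = 18,
                       trial_duration = 30,
                       fs = 50,
                       n_channels = 64,
                       noise_sd = 1,
                       confound = 0.35,
                       kernel_jitter = 0.3,
                       kernel_span = 0.4,
                       phoneme_rate = 5,
                       n_repetitions = 3,
                       dropout_prob = 0.2,
                       white_fraction = 0.1,
                       seed) {
  abort_if(missing(seed), "a master seed is mandatory")
  abort_if(any(session_gains < 0), "session gains must be >= 0")
  abort_if(length(session_gains) != length(sessions),
           "one gain per session required")
  abort_if(trial_duration <= 0 || fs <= 0, "durations and fs must be > 0")
  abort_if(n_channels < 8, "need at least 8 channels (incl. 2 mastoids + 4 facial)")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic phoneme sequence
#'
#' Non-overlapping alignments tiling `[0, duration]` with log-normal
#' phoneme durations and labels drawn from a configurable frequency
#' distribution over the inventory.
#'
#' @param inventory a [feature_inventory()].
#' @param rate mean phonemes per second.
#' @param duration sequence length in seconds.
#' @param seed integer seed.
#' @param label_weights optional named sampling weights (defaults to
#'   uniform over the inventory).
#' @return alignment data.frame (label/onset/offset).
#' @export
generate_phoneme_sequence <- function(inventory, rate, duration, seed,
                                      label_weights = NULL) {
  abort_if(rate <= 0, "rate must be > 0")
  abort_if(duration < 1 / rate, "duration too short for one phoneme")
  phonemes <- rownames(inventory)
  if (is.null(label_weights)) {
    label_weights <- rep(1, length(phonemes))
  } else {
    abort_if(!all(phonemes %in% names(label_weights)),
             "label_weights must cover the inventory")
    label_weights <- label_weights[phonemes]
  }
  probs <- label_weights / sum(label_weights)
  with_seed(seed, {
    sdlog <- 0.4
    meanlog <- log(1 / rate) - sdlog^2 / 2
    n_max <- ceiling(duration * rate * 3) + 10
    durs <- stats::rlnorm(n_max, meanlog, sdlog)
    ends <- cumsum(durs)
    keep <- ends <= duration
    durs <- durs[keep]
    abort_if(length(durs) == 0, "duration too short for one phoneme")
    onsets <- c(0, cumsum(durs)[-length(durs)])
    labels <- sample(phonemes, length(durs), replace = TRUE, prob = probs)
    validate_alignments(data.frame(label = labels, onset = onsets,
                                   offset = onsets + durs))
  })
}

# Smooth positive spectral template per phoneme (8 bands).
make_spectral_templates <- function(inventory, n_bands = 8, seed) {
  with_seed(seed, {
    t(vapply(rownames(inventory), function(ph) {
      raw <- stats::rnorm(n_bands)
      sm <- stats::filter(c(raw[1], raw, raw[n_bands]), rep(1 / 3, 3))
      log1p(exp(as.numeric(sm[2:(n_bands + 1)])))   # softplus > 0
    }, numeric(n_bands)))
  })
}

# Smooth nonnegative time series (low-passed white noise, rectified).
smooth_noise_series <- function(n, fs, cutoff = 4) {
  z <- stats::rnorm(n)
  if (cutoff < fs / 2) {
    bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
    z <- signal::filtfilt(bf, z)
  }
  z - min(z)
}

#' Generate correlated synthetic stimulus features
#'
#' F is built by the same [phonetic_feature_matrix()] pathway the real-data
#' branch uses. S mixes a phoneme-template-driven component (each phoneme
#' contributes its 8-band spectral template, modulated by a random prosodic
#' envelope) with independent smooth noise; the mixing weight is the
#' acoustic-confound strength, so S predicts F partially, as in real
#' speech. D is the half-wave-rectified derivative of the S row-sum; V is
#' smooth independent noise.
#'
#' @param alignments phoneme alignments (label/onset/offset).
#' @param inventory a [feature_inventory()].
#' @param templates phoneme x 8 positive matrix of spectral templates.
#' @param fs analysis rate in Hz.
#' @param duration trial duration in seconds.
#' @param confound mixing weight in `[0, 1]` of the phoneme-driven S
#'   component.
#' @param seed integer seed.
#' @param trial_id trial identifier.
#' @return a [stimulus_features()] object.
#' @export
generate_stimulus_features <- function(alignments, inventory, templates,
                                       fs, duration, confound, seed,
                                       trial_id = 1) {
  abort_if(!all(alignments$label %in% rownames(templates)),
           "every phoneme needs a spectral template")
  F_mat <- phonetic_feature_matrix(alignments, inventory, fs, duration)
  n <- nrow(F_mat)
  with_seed(seed, {
    prosody <- smooth_noise_series(n, fs, cutoff = 2) + 0.2
    S_phon <- matrix(0, n, ncol(templates))
    for (i in seq_len(nrow(alignments))) {
      i0 <- round_half_away(alignments$onset[i] * fs) + 1L
      i1 <- max(min(round_half_away(alignments$offset[i] * fs), n), i0)
      i0 <- min(i0, n)
      S_phon[i0:i1, ] <- S_phon[i0:i1, ] +
        rep(templates[alignments$label[i], ], each = i1 - i0 + 1L)
    }
    S_phon <- S_phon * prosody
    # light smoothing: band envelopes are sluggish
    bf <- signal::butter(2, min(8, fs / 2 * 0.8) / (fs / 2), type = "low")
    S_phon <- apply(S_phon, 2, function(col) signal::filtfilt(bf, col))
    S_noise <- vapply(seq_len(ncol(templates)),
                      function(b) smooth_noise_series(n, fs, cutoff = 4),
                      numeric(n))
    scl <- function(m) {
      s <- stats::sd(as.numeric(m)); if (s == 0) m else m / s
    }
    S <- confound * scl(S_phon) + (1 - confound) * scl(S_noise)
    S <- S - min(S)
    V <- smooth_noise_series(n, fs, cutoff = 3)
    ed <- envelope_and_derivative(S)
    stimulus_features(S = S, D = ed$D, F = F_mat, V = V, fs = fs,
                      trial_id = trial_id)
  })
}

# Cohort-level TRF kernels: per feature, a smooth temporal profile
# (mixture of 2 Gaussian bumps over the kernel span) times a smooth
# channel-loading profile. The channel profiles of one kernel set share a
# common smooth spatial map with modest per-feature deviations: responses
# to related features project through the same volume conduction, giving
# the consistent-polarity, highly similar topographies seen for auditory
# TRFs under a mastoid reference (the grand-average ground-truth trace is
# only meaningful in this regime). Returns feature x lag x channel array.
make_kernels <- function(n_features, kernel_lags, n_channels, seed) {
  L <- length(kernel_lags)
  smooth_prof <- function() {
    z <- stats::rnorm(n_channels)
    if (n_channels >= 5)
      z <- as.numeric(stats::filter(z, rep(1 / 5, 5), circular = TRUE))
    z / max(stats::sd(z), 1e-12)
  }
  with_seed(seed, {
    K <- array(0, dim = c(n_features, L, n_channels))
    common <- 1 + 0.4 * smooth_prof()
    for (f in seq_len(n_features)) {
      centers <- stats::runif(2, 0.15, 0.85) * (L - 1)
      widths <- stats::runif(2, 0.08, 0.2) * L
      # definite deflections (bounded away from zero), random polarity
      amps <- sample(c(-1, 1), 2, replace = TRUE) * stats::runif(2, 0.5, 1.5)
      temporal <- rowSums(vapply(1:2, function(j)
        amps[j] * exp(-((seq_len(L) - 1 - centers[j])^2) / (2 * widths[j]^2)),
        numeric(L)))
      prof <- common + 0.25 * smooth_prof()
      K[f, , ] <- outer(temporal, prof)
    }
    K / max(abs(K))
  })
}

# 1/f ("pink") noise via FFT shaping, mixed with a white component.
pink_noise <- function(n, white_fraction = 0.1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index
  shaped <- Re(stats::fft(W / sqrt(f), inverse = TRUE)) / n
  shaped <- shaped / stats::sd(shaped)
  white <- stats::rnorm(n)
  sqrt(1 - white_fraction) * shaped + sqrt(white_fraction) * white
}

#' Simulate one EEG recording from known kernels
#'
#' Each scalp channel is the sum over features of the lagged linear
#' convolution of the stimulus streams with that channel's kernels —
#' exactly the forward model the TRF estimator assumes — with the phonetic
#' kernels scaled by the session gain `g`, plus 1/f-spectrum noise scaled
#' relative to the clean signal SD. Mastoid channels carry an attenuated
#' copy of the mean scalp signal (reference-consistent); facial channels
#' carry noise only.
#'
#' @param features a [stimulus_features()] object.
#' @param truth kernel set as returned by the cohort generator: list with
#'   `K_S` (8 x L x channels), `K_F` (14 x L x channels), `kernel_lags`.
#' @param g phonetic kernel gain for this session.
#' @param noise_sd noise SD relative to clean signal SD.
#' @param seed integer seed.
#' @param layout channel layout list (`scalp`, `mastoid`, `facial` labels)
#'   as built by the cohort generator; `NULL` for scalp-only output.
#' @param white_fraction white share of the noise power.
#' @return an [eeg_recording()] (channels x time).
#' @export
simulate_eeg_from_kernels <- function(features, truth, g, noise_sd, seed,
                                      layout = NULL, white_fraction = 0.1) {
  abort_if(anyNA(truth$K_S) || anyNA(truth$K_F), "kernels must be finite")
  kw <- structure(list(lags = truth$kernel_lags), class = "lag_window")
  X_S <- lag_design_matrix(features$S, kw)
  X_F <- lag_design_matrix(features$F, kw)
  n_ch <- dim(truth$K_S)[3]
  L <- length(truth$kernel_lags)
  W_S <- matrix(aperm(truth$K_S, c(2, 1, 3)), ncol = n_ch)
  W_F <- matrix(aperm(truth$K_F, c(2, 1, 3)), ncol = n_ch)
  clean <- X_S %*% W_S + g * (X_F %*% W_F)     # time x scalp channels
  sig_sd <- stats::sd(as.numeric(clean))
  if (sig_sd == 0) sig_sd <- 1
  n <- nrow(clean)
  if (is.null(layout)) {
    labels <- paste0("E", seq_len(n_ch))
    data <- t(clean)
  } else {
    labels <- c(layout$scalp, layout$mastoid, layout$facial)
    mast <- 0.2 * rowMeans(clean)
    data <- rbind(t(clean),
                  matrix(rep(mast, length(layout$mastoid)),
                         nrow = length(layout$mastoid), byrow = TRUE),
                  matrix(0, length(layout$facial), n))
  }
  data <- with_seed(seed, {
    noise <- t(vapply(seq_len(nrow(data)),
                      function(ch) pink_noise(n, white_fraction),
                      numeric(n)))
    data + noise_sd * sig_sd * noise
  })
  eeg_recording(data, fs = features$fs, channel_labels = labels,
                mastoid_labels = layout$mastoid,
                facial_labels = layout$facial,
                trial_id = features$trial_id)
}

# Synthetic montage: scalp electrodes on the upper hemisphere (golden-angle
# spiral), mastoids low behind the "ears", facial electrodes low frontal.
synthetic_montage <- function(layout) {
  n_s <- length(layout$scalp)
  i <- seq_len(n_s)
  z <- i / (n_s + 1)
  theta <- i * pi * (3 - sqrt(5))
  r <- sqrt(1 - z^2)
  pos <- data.frame(label = layout$scalp,
                    x = r * cos(theta), y = r * sin(theta), z = z)
  extra <- data.frame(
    label = c(layout$mastoid, layout$facial),
    x = c(-0.95, 0.95, -0.3, -0.1, 0.1, 0.3)[seq_len(length(layout$mastoid) +
                                                       length(layout$facial))],
    y = c(0, 0, 0.95, 0.99, 0.99, 0.95)[seq_len(length(layout$mastoid) +
                                                  length(layout$facial))],
    z = c(-0.25, -0.25, -0.2, -0.2, -0.2, -0.2)[seq_len(length(layout$mastoid) +
                                                          length(layout$facial))])
  rbind(pos, extra)
}

channel_layout <- function(n_channels) {
  n_scalp <- n_channels - 6L
  list(scalp = paste0("E", seq_len(n_scalp)),
       mastoid = c("M1", "M2"),
       facial = paste0("FAC", 1:4))
}

#' Simulate a longitudinal synthetic cohort
#'
#' Generates, per participant and session, trial-wise stimulus features and
#' repeated EEG presentations from participant-specific kernels (cohort
#' kernels plus smooth jitter) with the session's phonetic gain. All
#' randomness is derived deterministically from the master seed. The hidden
#' kernels and gains are returned separately as `truth` and are never read
#' by the estimation path.
#'
#' @param config a [sim_config()].
#' @return list with `data` (participants -> sessions -> trials, plus the
#'   montage and layout) and `truth` (cohort/participant kernels, gains,
#'   seeds).
#' @export
simulate_longitudinal_cohort <- function(config) {
  abort_if(!inherits(config, "sim_config"), "config must be a sim_config")
  inv <- default_feature_inventory()
  master <- config$seed
  layout <- channel_layout(config$n_channels)
  n_scalp <- length(layout$scalp)
  L_k <- round_half_away(config$kernel_span * config$fs) + 1L
  kernel_lags <- seq.int(0L, L_k - 1L)
  templates <- make_spectral_templates(inv, 8, derive_seed(master, "templates"))
  K_S <- make_kernels(8, kernel_lags, n_scalp, derive_seed(master, "K_S"))
  K_F <- make_kernels(14, kernel_lags, n_scalp, derive_seed(master, "K_F"))
  # calibrate the phonetic kernels so that gain g means "phonetic drive with
  # g times the RMS of the acoustic drive" on a reference stimulus; one
  # cohort-level constant, so the forward model stays fixed across trials
  calib_al <- generate_phoneme_sequence(inv, config$phoneme_rate,
                                        max(config$trial_duration, 10),
                                        derive_seed(master, "calib/seq"))
  calib_ft <- generate_stimulus_features(calib_al, inv, templates, config$fs,
                                         max(config$trial_duration, 10),
                                         config$confound,
                                         derive_seed(master, "calib/stim"))
  kw <- structure(list(lags = kernel_lags), class = "lag_window")
  part_S <- lag_design_matrix(calib_ft$S, kw) %*%
    matrix(aperm(K_S, c(2, 1, 3)), ncol = n_scalp)
  part_F <- lag_design_matrix(calib_ft$F, kw) %*%
    matrix(aperm(K_F, c(2, 1, 3)), ncol = n_scalp)
  sd_F <- stats::sd(as.numeric(part_F))
  if (sd_F > 0) K_F <- K_F * stats::sd(as.numeric(part_S)) / sd_F
  montage <- synthetic_montage(layout)

  participant_ids <- paste0("P", sprintf("%02d", seq_len(config$n_participants)))
  abort_if(anyDuplicated(participant_ids) > 0, "duplicate participant ids")

  participants <- lapply(seq_len(config$n_participants), function(pi) {
    pid <- participant_ids[pi]
    jit_seed <- derive_seed(master, paste0(pid, "/jitter"))
    K_S_p <- K_S + config$kernel_jitter *
      make_kernels(8, kernel_lags, n_scalp, jit_seed)
    K_F_p <- K_F + config$kernel_jitter *
      make_kernels(14, kernel_lags, n_scalp, derive_seed(master,
                                                         paste0(pid, "/jitterF")))
    truth_p <- list(K_S = K_S_p, K_F = K_F_p, kernel_lags = kernel_lags)
    sessions <- lapply(seq_along(config$sessions), function(si) {
      ses <- config$sessions[si]
      g <- config$session_gains[si]
      trials <- lapply(seq_len(config$n_trials), function(ti) {
        key <- paste0(pid, "/", ses, "/trial", ti)
        al <- generate_phoneme_sequence(inv, config$phoneme_rate,
                                        config$trial_duration,
                                        derive_seed(master,
                                                    paste0(key, "/seq")))
        ft <- generate_stimulus_features(al, inv, templates, config$fs,
                                         config$trial_duration,
                                         config$confound,
                                         derive_seed(master,
                                                     paste0(key, "/stim")),
                                         trial_id = ti)
        n_rep <- config$n_repetitions
        if (config$n_repetitions > 1 && config$dropout_prob > 0) {
          drop <- with_seed(derive_seed(master, paste0(key, "/drop")),
                            stats::runif(1) < config$dropout_prob)
          if (drop) n_rep <- n_rep - 1L
        }
        reps <- lapply(seq_len(n_rep), function(ri) {
          e <- simulate_eeg_from_kernels(
            ft, truth_p, g, config$noise_sd,
            derive_seed(master, paste0(key, "/noise/rep", ri)),
            layout = layout, white_fraction = config$white_fraction)
          e$participant_id <- pid
          e$session <- ses
          e$repetition <- ri
          e$montage <- montage
          e
        })
        list(features = ft, repetitions = reps)
      })
      list(session = ses, trials = trials)
    })
    list(participant_id = pid, sessions = sessions)
  })

  truth <- structure(list(K_S = K_S, K_F = K_F, kernel_lags = kernel_lags,
                          session_gains = config$session_gains,
                          kernel_jitter = config$kernel_jitter,
                          master_seed = master),
                     class = "sim_truth")
  list(data = list(participants = participants, montage = montage,
                   layout = layout, sessions = config$sessions,
                   fs = config$fs, config = config),
       truth = truth)
}
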