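# EEG conditioning chain: zero-phase Butterworth filtering, resampling,
# bad-channel interpolation, mastoid re-referencing, trial averaging,
# band-specific ground-truth traces and the first-word ERP SNR control.

#' Zero-phase Butterworth filter
#'
#' Order-`order` Butterworth designed for the requested band and applied
#' forward and backward (`signal::filtfilt`), so the effective magnitude
#' response is squared and the net phase shift is zero. Either cutoff may
#' be omitted for a pure low-/high-pass.
#'
#' @param x numeric signal (vector) or channels x time matrix (filtered
#'   row-wise).
#' @param low,high cutoff frequencies in Hz (either may be `NULL`).
#' @param order filter order (default 2, as used throughout the pipeline).
#' @param fs sampling rate in Hz.
#' @return filtered signal, same shape as `x`.
#' @export
zero_phase_bandpass <- function(x, low = NULL, high = NULL, order = 2, fs) {
  nyq <- fs / 2
  for (f in c(low, high))
    abort_if(f <= 0 || f >= nyq, "cutoffs must lie in (0, Nyquist)")
  abort_if(is.null(low) && is.null(high), "need at least one cutoff")
  bf <- if (!is.null(low) && !is.null(high)) {
    abort_if(low >= high, "low cutoff must be below high cutoff")
    signal::butter(order, c(low, high) / nyq, type = "pass")
  } else if (!is.null(high)) {
    signal::butter(order, high / nyq, type = "low")
  } else {
    signal::butter(order, low / nyq, type = "high")
  }
  if (is.matrix(x)) {
    t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Downsample a signal
#'
#' Zero-phase anti-alias low-pass (4th-order Butterworth at 0.45 of the new
#' Nyquist-doubling rate) followed by exact-time interpolation onto the new
#' sample grid, so the output carries no group delay. Output length is
#' `round(n * fs_out / fs_in)`.
#'
#' @param x vector or channels x time matrix.
#' @param fs_in,fs_out sampling rates in Hz, `fs_out <= fs_in`.
#' @return resampled signal.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  abort_if(fs_out > fs_in, "upsampling is out of contract (fs_out > fs_in)")
  if (fs_in == fs_out) return(x)
  if (is.matrix(x))
    return(t(apply(x, 1, resample_signal, fs_in = fs_in, fs_out = fs_out)))
  lp <- signal::butter(4, 0.9 * fs_out / fs_in, type = "low")
  y <- signal::filtfilt(lp, x)
  n_out <- round_half_away(length(x) * fs_out / fs_in)
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, y, xout = pmin(t_out, t_in[length(t_in)]))$y
}

#' Detect and interpolate bad channels
#'
#' Channels whose amplitude-distribution statistics deviate from the rest of
#' the montage are flagged and rebuilt from clean neighbours. Two per-channel
#' statistics are screened: excess kurtosis and log-variance; a channel is
#' flagged when either z-score (against the across-channel distribution)
#' exceeds `z_threshold`. Flagged channels are replaced by inverse-distance
#' weighted averages of their `k` nearest clean channels on the 3-D montage
#' (an approximation of spherical-spline interpolation).
#'
#' @param eeg an [eeg_recording()] with a montage (label/x/y/z).
#' @param z_threshold flagging threshold in SD units (default 3).
#' @param k number of clean neighbours used for interpolation.
#' @return list with `eeg` (repaired recording) and `flagged` (labels).
#' @export
interpolate_bad_channels <- function(eeg, z_threshold = 3, k = 4) {
  abort_if(is.null(eeg$montage), "montage with channel positions required")
  m <- eeg$montage
  abort_if(!all(eeg$channel_labels %in% m$label),
           "montage must provide a position for every channel")
  X <- eeg$data
  kurt <- apply(X, 1, function(v) {
    s2 <- stats::var(v); if (s2 == 0) return(0)
    mean((v - mean(v))^4) / s2^2 - 3
  })
  logvar <- apply(X, 1, function(v) log(stats::var(v) + .Machine$double.eps))
  z <- function(v) (v - mean(v)) / (stats::sd(v) + .Machine$double.eps)
  bad <- abs(z(kurt)) > z_threshold | abs(z(logvar)) > z_threshold
  abort_if(mean(bad) > 0.5,
           paste0("more than half the channels flagged bad (",
                  sum(bad), "/", length(bad), "); aborting"))
  if (any(bad)) {
    pos <- as.matrix(m[match(eeg$channel_labels, m$label), c("x", "y", "z")])
    good_idx <- which(!bad)
    for (b in which(bad)) {
      d <- sqrt(colSums((t(pos[good_idx, , drop = FALSE]) - pos[b, ])^2))
      nb <- good_idx[order(d)][seq_len(min(k, length(good_idx)))]
      w <- 1 / (sort(d)[seq_along(nb)] + .Machine$double.eps)
      X[b, ] <- colSums(X[nb, , drop = FALSE] * (w / sum(w)))
    }
  }
  out <- eeg
  out$data <- X
  list(eeg = out, flagged = eeg$channel_labels[bad])
}

#' Drop facial channels
#'
#' Facial electrodes are not part of the infant-sized net and are excluded
#' from all analyses.
#'
#' @param eeg an [eeg_recording()].
#' @param facial_labels labels to drop; defaults to `eeg$facial_labels`.
#' @return the recording without the facial channels.
#' @export
drop_facial_channels <- function(eeg, facial_labels = eeg$facial_labels) {
  if (is.null(facial_labels) || length(facial_labels) == 0) return(eeg)
  keep <- !eeg$channel_labels %in% facial_labels
  out <- eeg
  out$data <- eeg$data[keep, , drop = FALSE]
  out$channel_labels <- eeg$channel_labels[keep]
  out$facial_labels <- NULL
  out
}

#' Re-reference to the mastoid average and drop the mastoids
#'
#' Every remaining channel has the mean of the two mastoid channels
#' subtracted; the mastoid channels are then removed. Mastoid referencing is
#' what makes the all-channel grand average (ground-truth EEG) meaningful —
#' under a global average reference the across-channel mean would be zero
#' by construction.
#'
#' @param eeg an [eeg_recording()] whose `mastoid_labels` are present.
#' @return the re-referenced recording (mastoids removed).
#' @export
rereference_to_mastoids <- function(eeg) {
  ml <- eeg$mastoid_labels
  abort_if(is.null(ml) || !all(ml %in% eeg$channel_labels),
           "both mastoid labels must be present")
  ref <- colMeans(eeg$data[ml, , drop = FALSE])
  keep <- !eeg$channel_labels %in% ml
  out <- eeg
  out$data <- sweep(eeg$data[keep, , drop = FALSE], 2, ref)
  out$channel_labels <- eeg$channel_labels[keep]
  out$mastoid_labels <- NULL
  out
}

#' Average repeated presentations of a trial
#'
#' @param repetitions list of [eeg_recording()]s with identical shape and
#'   labels (infants typically contribute 2 repetitions, adults 3).
#' @return an [eeg_recording()] holding the sample-wise mean, with
#'   `n_repetitions` recording how many went in.
#' @export
average_trials <- function(repetitions) {
  abort_if(length(repetitions) < 1, "need at least one repetition")
  ref <- repetitions[[1]]
  for (r in repetitions[-1]) {
    abort_if(!identical(dim(r$data), dim(ref$data)) ||
               !identical(r$channel_labels, ref$channel_labels),
             "repetitions must share shape and channel labels")
  }
  out <- ref
  out$data <- Reduce(`+`, lapply(repetitions, `[[`, "data")) /
    length(repetitions)
  out$n_repetitions <- length(repetitions)
  out$repetition <- NA
  out
}

#' Band-specific ground-truth EEG trace
#'
#' The grand-average EEG across all channels and all participants in a
#' group, band-pass filtered to one of the analysis bands. Every
#' participant's prediction is correlated against this single shared trace,
#' which removes between-participant SNR differences from the score.
#'
#' @param cohort list of [eeg_recording()]s (one per participant) for the
#'   same trial, already preprocessed.
#' @param band length-2 numeric `c(low, high)` in Hz, or `NULL` for no
#'   band filtering.
#' @param order Butterworth order for the band filter.
#' @return numeric vector: the single ground-truth trace.
#' @export
ground_truth_average <- function(cohort, band = NULL, order = 2) {
  abort_if(length(cohort) == 0, "empty cohort")
  traces <- vapply(cohort, function(e) colMeans(e$data),
                   numeric(ncol(cohort[[1]]$data)))
  g <- rowMeans(traces)
  if (!is.null(band))
    g <- zero_phase_bandpass(g, band[1], band[2], order = order,
                             fs = cohort[[1]]$fs)
  g
}

#' First-word ERP signal-to-noise ratio
#'
#' Ratio of post- to pre-onset mean squared amplitude of the event-related
#' potential around the first word of a trial, pooled over channels. Used as
#' a control that group differences in encoding are not mere SNR differences.
#'
#' @param eeg an [eeg_recording()] (already trial-averaged).
#' @param onset first-word onset in seconds.
#' @param pre_window,post_window window lengths in seconds.
#' @return scalar SNR (power ratio).
#' @export
snr_first_word <- function(eeg, onset, pre_window = 0.5, post_window = 0.5) {
  fs <- eeg$fs
  i_on <- round_half_away(onset * fs) + 1L
  i_pre <- (i_on - round_half_away(pre_window * fs)):(i_on - 1L)
  i_post <- i_on:(i_on + round_half_away(post_window * fs) - 1L)
  abort_if(min(i_pre) < 1 || max(i_post) > ncol(eeg$data),
           "windows do not fit within the trial")
  pre_p <- mean(eeg$data[, i_pre, drop = FALSE]^2)
  post_p <- mean(eeg$data[, i_post, drop = FALSE]^2)
  abort_if(pre_p == 0, "zero pre-stimulus power (degenerate input)")
  post_p / pre_p
}

#' Run the full preprocessing chain on one recording
#'
#' Order of operations: facial-channel exclusion, low-pass (8 Hz), high-pass
#' (0.1 Hz), downsample to the analysis rate, artifact-cleaning hook,
#' bad-channel interpolation, mastoid re-referencing. Band-specific
#' (low-delta / delta / theta) filtering is applied downstream.
#'
#' @param eeg raw [eeg_recording()].
#' @param lowpass,highpass broadband filter cutoffs in Hz.
#' @param fs_out analysis rate in Hz.
#' @param filter_order Butterworth order.
#' @param artifact_hook optional function `eeg -> eeg` run after resampling
#'   (e.g. an external artifact-subspace cleaner); default pass-through.
#' @param interpolate whether to run bad-channel detection/interpolation
#'   (requires a montage).
#' @return list with `eeg` (preprocessed) and `flagged` (bad channels).
#' @export
preprocess_recording <- function(eeg, lowpass = 8, highpass = 0.1,
                                 fs_out = 50, filter_order = 2,
                                 artifact_hook = NULL, interpolate = TRUE) {
  x <- drop_facial_channels(eeg)
  if (!is.null(lowpass) && lowpass < x$fs / 2)
    x$data <- zero_phase_bandpass(x$data, high = lowpass,
                                  order = filter_order, fs = x$fs)
  if (!is.null(highpass))
    x$data <- zero_phase_bandpass(x$data, low = highpass,
                                  order = filter_order, fs = x$fs)
  if (fs_out < x$fs) {
    x$data <- resample_signal(x$data, x$fs, fs_out)
    x$fs <- fs_out
  }
  if (!is.null(artifact_hook)) x <- artifact_hook(x)
  flagged <- character(0)
  if (interpolate && !is.null(x$montage)) {
    res <- interpolate_bad_channels(x)
    x <- res$eeg
    flagged <- res$flagged
  }
  x <- rereference_to_mastoids(x)
  list(eeg = x, flagged = flagged)
}
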