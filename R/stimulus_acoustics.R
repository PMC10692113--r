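# Acoustic stimulus representations: Greenwood-spaced auditory spectrogram,
# broadband envelope and its half-wave-rectified derivative, visual motion.

#' Greenwood-spaced filterbank band edges
#'
#' Computes `n_bands + 1` band-edge frequencies equally spaced in cochlear
#' position under the human Greenwood map `F(x) = A (10^(a x) - k)` with
#' `x` the normalised basilar-membrane position in `[0, 1]`. The defaults
#' are the standard human constants.
#'
#' @param fmin,fmax frequency range in Hz (`0 < fmin < fmax`).
#' @param n_bands number of bands (>= 1).
#' @param A,a,k Greenwood constants for the human cochlea.
#' @return numeric vector of `n_bands + 1` strictly increasing edges, with
#'   `edges[1] == fmin` and `edges[n_bands + 1] == fmax`.
#' @export
#' @examples
#' greenwood_band_edges(250, 8000, 8)
greenwood_band_edges <- function(fmin, fmax, n_bands,
                                 A = 165.4, a = 2.1, k = 0.88) {
  abort_if(!is.numeric(fmin) || !is.numeric(fmax) || fmin <= 0 || fmax <= fmin,
           "need 0 < fmin < fmax")
  abort_if(n_bands < 1, "n_bands must be >= 1")
  pos <- function(f) log10(f / A + k) / a      # inverse Greenwood map
  x <- seq(pos(fmin), pos(fmax), length.out = n_bands + 1)
  edges <- A * (10^(a * x) - k)
  # pin the outer edges to the requested range exactly
  edges[1] <- fmin
  edges[n_bands + 1] <- fmax
  edges
}

# FFT-based analytic-signal magnitude (envelope). Standard construction:
# zero the negative frequencies, double the positive ones, inverse FFT.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Multi-band amplitude-envelope spectrogram
#'
#' Filters the waveform into `length(edges) - 1` bands (4th-order zero-phase
#' Butterworth band-pass per band), takes the magnitude of the analytic
#' signal as the band envelope, anti-alias low-pass filters it and resamples
#' to the analysis rate. Amplitudes are linear (no compression).
#'
#' @param audio numeric waveform (mono).
#' @param fs_audio audio sampling rate in Hz; must exceed twice the top edge.
#' @param edges band edge frequencies, as from [greenwood_band_edges()].
#' @param fs_out analysis sampling rate in Hz.
#' @return time x n_bands nonnegative matrix.
#' @export
acoustic_spectrogram <- function(audio, fs_audio, edges, fs_out) {
  abort_if(fs_audio <= 2 * edges[length(edges)],
           "fs_audio must exceed twice the highest band edge (Nyquist)")
  abort_if(fs_out > fs_audio, "fs_out must not exceed fs_audio")
  n_out <- round_half_away(length(audio) / fs_audio * fs_out)
  abort_if(n_out < 1, "audio shorter than one output sample")
  n_bands <- length(edges) - 1
  S <- matrix(0, n_out, n_bands)
  if (all(audio == 0)) return(S)
  for (b in seq_len(n_bands)) {
    bf <- signal::butter(2, c(edges[b], edges[b + 1]) / (fs_audio / 2),
                         type = "pass")
    band <- signal::filtfilt(bf, audio)   # applied twice -> 4th order, zero phase
    env <- analytic_envelope(band)
    # anti-alias before decimation
    lp <- signal::butter(4, min(0.8 * fs_out / 2, fs_audio / 2 * 0.99) /
                           (fs_audio / 2), type = "low")
    env <- signal::filtfilt(lp, env)
    S[, b] <- resample_to_length(env, n_out)
  }
  S[S < 0] <- 0
  S
}

# Resample a vector to an exact target length (polyphase when the ratio is
# rational with small terms, linear interpolation of the time base otherwise).
resample_to_length <- function(x, n_out) {
  n_in <- length(x)
  if (n_in == n_out) return(x)
  stats::approx(seq(0, 1, length.out = n_in), x,
                xout = seq(0, 1, length.out = n_out))$y
}

#' Broadband envelope and half-wave-rectified derivative
#'
#' The broadband envelope is the row-sum of the band spectrogram; the onset
#' regressor D is the first difference of that envelope with negative values
#' clipped to zero (first sample defined as 0).
#'
#' @param S time x bands nonnegative matrix.
#' @return list with `env` and `D`, both of length `nrow(S)`.
#' @export
envelope_and_derivative <- function(S) {
  abort_if(!is.matrix(S) || nrow(S) == 0, "S must be a non-empty matrix")
  abort_if(any(S < 0), "S must be nonnegative")
  env <- rowSums(S)
  D <- c(0, pmax(diff(env), 0))
  list(env = env, D = D)
}

#' Visual motion regressor from per-frame luminance
#'
#' Mean absolute frame-to-frame luminance change, resampled to the analysis
#' rate and length-matched to the trial duration. The first value is 0.
#'
#' @param luminance numeric vector of per-frame mean luminance values.
#' @param frame_rate video frame rate in Hz.
#' @param fs_out analysis rate in Hz.
#' @param duration trial duration in seconds.
#' @return nonnegative vector of length `round(duration * fs_out)`.
#' @export
visual_motion_regressor <- function(luminance, frame_rate, fs_out, duration) {
  abort_if(length(luminance) < 2, "need at least 2 frames")
  v <- c(0, abs(diff(luminance)))
  n_out <- round_half_away(duration * fs_out)
  out <- resample_to_length(v, n_out)
  out[out < 0] <- 0
  out
}
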