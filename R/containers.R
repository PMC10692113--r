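# Core data containers: stimulus feature bundles and EEG recordings.

#' Bundle the four time-aligned stimulus regressor streams
#'
#' @param S time x bands nonnegative spectrogram matrix.
#' @param D nonnegative envelope-derivative vector.
#' @param F time x 14 binary phonetic feature matrix.
#' @param V nonnegative visual motion vector.
#' @param fs analysis rate in Hz.
#' @param trial_id trial identifier.
#' @return a `stimulus_features` object (list).
#' @export
stimulus_features <- function(S, D, F, V, fs, trial_id = 1) {
  abort_if(fs <= 0, "fs must be positive")
  n <- nrow(S)
  abort_if(length(D) != n || nrow(F) != n || length(V) != n,
           "S, D, F, V must share one length")
  abort_if(ncol(F) != 14, "F must have 14 columns")
  abort_if(!all(F %in% c(0L, 1L)), "F entries must be binary")
  abort_if(any(S < 0) || any(D < 0) || any(V < 0),
           "S, D and V must be nonnegative")
  structure(list(S = S, D = D, F = F, V = V, fs = fs, trial_id = trial_id),
            class = "stimulus_features")
}

#' @export
print.stimulus_features <- function(x, ...) {
  cat(sprintf(
    "<stimulus_features> trial %s: %d samples @ %g Hz (%.1f s), %d bands + D + 14 features + V\n",
    x$trial_id, nrow(x$S), x$fs, nrow(x$S) / x$fs, ncol(x$S)))
  invisible(x)
}

#' Construct a multi-channel EEG recording
#'
#' @param data channels x time matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_labels unique channel names (default E1..En).
#' @param mastoid_labels length-2 vector naming the mastoid pair (or NULL).
#' @param facial_labels channels to exclude from analysis (or NULL).
#' @param participant_id,session,trial_id,repetition metadata.
#' @param montage optional data.frame with columns label/x/y/z.
#' @param n_repetitions number of repetitions averaged into this recording.
#' @return an `eeg_recording` object (list).
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          mastoid_labels = NULL, facial_labels = NULL,
                          participant_id = NA, session = NA, trial_id = NA,
                          repetition = 1L, montage = NULL,
                          n_repetitions = 1L) {
  data <- as.matrix(data)
  abort_if(fs <= 0, "fs must be positive")
  if (is.null(channel_labels))
    channel_labels <- paste0("E", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  abort_if(length(channel_labels) != nrow(data),
           "one label per channel required")
  abort_if(anyDuplicated(channel_labels) > 0, "channel labels must be unique")
  abort_if(anyNA(data), "EEG data must not contain NaN/NA")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 mastoid_labels = mastoid_labels,
                 facial_labels = facial_labels,
                 participant_id = participant_id, session = session,
                 trial_id = trial_id, repetition = repetition,
                 montage = montage, n_repetitions = n_repetitions),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz | participant %s, session %s, trial %s\n",
    nrow(x$data), ncol(x$data), x$fs, x$participant_id, x$session, x$trial_id))
  invisible(x)
}
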