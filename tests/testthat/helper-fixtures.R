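# Shared fixtures and oracles built in code at test time.

# brute-force two-tailed signed-rank p by enumerating all 2^n sign patterns
enumerate_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  rk <- rank(abs(x))
  v_obs <- sum(rk[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% rk
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# Write a minimal long-format TextGrid with the given intervals on a
# "phones" tier (plus a distractor point-free word tier before it).
write_textgrid_fixture <- function(path, intervals, xmax = NULL) {
  if (is.null(xmax)) xmax <- max(intervals$offset)
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    '',
    'xmin = 0',
    paste0('xmax = ', xmax),
    'tiers? <exists>',
    'size = 2',
    'item []:',
    '    item [1]:',
    '        class = "IntervalTier"',
    '        name = "words"',
    '        xmin = 0',
    paste0('        xmax = ', xmax),
    '        intervals: size = 1',
    '        intervals [1]:',
    '            xmin = 0',
    paste0('            xmax = ', xmax),
    '            text = "la"',
    '    item [2]:',
    '        class = "IntervalTier"',
    '        name = "phones"',
    '        xmin = 0',
    paste0('        xmax = ', xmax),
    paste0('        intervals: size = ', nrow(intervals)))
  for (i in seq_len(nrow(intervals))) {
    lines <- c(lines,
               paste0('        intervals [', i, ']:'),
               paste0('            xmin = ', intervals$onset[i]),
               paste0('            xmax = ', intervals$offset[i]),
               paste0('            text = "', intervals$label[i], '"'))
  }
  writeLines(lines, path)
  path
}

# A tiny single-session cohort for pipeline-level tests.
tiny_sim_block <- function(n = 4, sessions = c("4mo", "11mo"),
                           gains = c(0, 1), trials = 2, dur = 6,
                           nch = 14, reps = 2) {
  list(n_participants = n, sessions = sessions, session_gains = gains,
       n_trials = trials, trial_duration = dur, fs = 25, n_channels = nch,
       noise_sd = 1, n_repetitions = reps, dropout_prob = 0)
}

# Per-participant x session FS-S gains for a simulated cohort, via the
# package pipeline (delta band only, gain models only).
gain_run_config <- function(seed, sim) {
  cfg <- default_run_config(seed, simulate = sim)
  cfg$bands <- list(delta = c(1, 4))
  cfg$models_single <- list()
  cfg$gain_band_selection <- FALSE
  cfg$lambda_grid <- 10^c(0, 2.5, 5)
  cfg$preprocess <- list(lowpass = NULL, highpass = NULL, fs_out = 25,
                         order = 2, interpolate = FALSE)
  cfg$snr <- NULL
  cfg
}

gains_matrix <- function(bundle, sessions) {
  g <- bundle$gains
  vapply(sessions, function(s) g$gain[g$session == s],
         numeric(length(unique(g$participant))))
}
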