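# End-to-end orchestration: config validation, staged execution
# (simulate/load -> preprocess -> fit -> gains -> stats), and report export.

#' Default analysis configuration
#'
#' Returns the full run configuration with the study's analysis parameters:
#' lowdelta/delta/theta bands, a -100..500 ms lag window, a lambda grid of
#' powers of 10 from 1e-2 to 1e6, single-feature models S and F, and the
#' acoustic-phonetic vs acoustic-only gain contrast.
#'
#' @param seed master seed for the run.
#' @param simulate named list of [sim_config()] overrides (a `simulate`
#'   block makes the run self-contained; otherwise set `paths$cohort_dir`).
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed, simulate = list()) {
  structure(list(
    simulate = simulate,
    paths = NULL,
    bands = list(lowdelta = c(0.1, 1), delta = c(1, 4), theta = c(4, 8)),
    lag_window = c(-0.1, 0.5),
    lambda_grid = 10^seq(-2, 6),
    penalty = "identity",
    models_single = list(S = "S", F = "F"),
    models_gain = list(full = c("S", "D", "V", "F"),
                       reduced = c("S", "D", "V")),
    gain_band_selection = TRUE,
    alpha = 0.05,
    bootstrap = list(group_size = 17, iterations = 100),
    snr = list(onset = 1, pre_window = 0.5, post_window = 0.5),
    preprocess = list(lowpass = 8, highpass = 0.1, fs_out = 50, order = 2,
                      interpolate = TRUE),
    seed = seed
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Schema violations raise an error before any computation.
#'
#' @param config a `run_config` (e.g. from [default_run_config()], possibly
#'   modified).
#' @return the validated config, invisibly.
#' @export
validate_run_config <- function(config) {
  required <- c("bands", "lag_window", "lambda_grid", "models_gain",
                "alpha", "preprocess", "seed")
  missing <- required[!vapply(required, function(f)
    !is.null(config[[f]]), logical(1))]
  abort_if(length(missing) > 0,
           paste("config schema violation: missing", paste(missing,
                                                           collapse = ", ")))
  abort_if(length(config$lambda_grid) == 0,
           "config schema violation: empty lambda grid")
  abort_if(length(config$lag_window) != 2 ||
             config$lag_window[1] >= config$lag_window[2],
           "config schema violation: lag_window must be (tmin, tmax)")
  b <- config$bands
  abort_if(length(b) == 0, "config schema violation: no bands")
  lims <- do.call(rbind, b)
  abort_if(any(lims[, 1] >= lims[, 2]),
           "config schema violation: band limits must be increasing")
  if (length(b) > 1) {
    ord <- order(lims[, 1])
    abort_if(any(lims[ord, 2][-length(b)] > lims[ord, 1][-1] + 1e-9),
             "config schema violation: bands must be non-overlapping")
  }
  all_feats <- c("S", "D", "V", "F")
  for (m in c(config$models_single, config$models_gain))
    abort_if(!all(m %in% all_feats),
             "config schema violation: model names only available features")
  abort_if(length(config$simulate) == 0 && is.null(config$paths),
           "config schema violation: need a simulate block or paths")
  invisible(config)
}

# Preprocess one participant-session: filter each repetition, average
# repetitions per trial, flag/interpolate bad channels on the concatenated
# session, re-reference to mastoids. Returns per-trial recordings + flags.
preprocess_session <- function(trials, pp) {
  filtered <- lapply(trials, function(tr) {
    reps <- lapply(tr$repetitions, function(e) {
      x <- drop_facial_channels(e)
      if (!is.null(pp$lowpass) && pp$lowpass < x$fs / 2)
        x$data <- zero_phase_bandpass(x$data, high = pp$lowpass,
                                      order = pp$order, fs = x$fs)
      if (!is.null(pp$highpass))
        x$data <- zero_phase_bandpass(x$data, low = pp$highpass,
                                      order = pp$order, fs = x$fs)
      if (pp$fs_out < x$fs) {
        x$data <- resample_signal(x$data, x$fs, pp$fs_out)
        x$fs <- pp$fs_out
      }
      x
    })
    average_trials(reps)
  })
  flagged <- character(0)
  if (isTRUE(pp$interpolate) && !is.null(filtered[[1]]$montage)) {
    concat <- filtered[[1]]
    concat$data <- do.call(cbind, lapply(filtered, `[[`, "data"))
    res <- interpolate_bad_channels(concat)
    flagged <- res$flagged
    if (length(flagged) > 0) {
      lens <- vapply(filtered, function(e) ncol(e$data), integer(1))
      splits <- split(seq_len(sum(lens)), rep(seq_along(lens), lens))
      for (i in seq_along(filtered))
        filtered[[i]]$data <- res$eeg$data[, splits[[i]], drop = FALSE]
    }
  }
  out <- lapply(filtered, rereference_to_mastoids)
  list(trials = out, flagged = flagged)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain the cohort (simulate block or fixture
#' directory), preprocess every recording, compute per-band ground-truth
#' traces, fit the single-feature TRF models (S, F) and the gain contrast
#' (acoustic-phonetic vs acoustic-only), then run the statistical battery
#' (screened group tests per band/model, one-sample and paired Wilcoxon on
#' gains with joint FDR, topography bootstrap against the reference group,
#' first-word ERP SNR control).
#'
#' By default the gain contrast is evaluated only in bands whose TRF_F
#' scores show a significant age effect on this run's own data (the
#' conditional flow); set `gain_band_selection = FALSE` to analyse all
#' bands.
#'
#' @param config a `run_config`; validated before any compute.
#' @return a `results_bundle`: list of tidy tables (`scores`, `gains`,
#'   `stats`, `snr`), per-group topography matrices, and a provenance
#'   record.
#' @export
run_full_analysis <- function(config) {
  validate_run_config(config)

  # ---- stage: data ----
  if (length(config$simulate) > 0) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cohort <- simulate_longitudinal_cohort(do.call(sim_config, sim_args))$data
  } else {
    cohort <- read_cohort_dir(config$paths$cohort_dir)
  }
  sessions <- cohort$sessions
  n_part <- length(cohort$participants)
  part_ids <- vapply(cohort$participants, `[[`, character(1),
                     "participant_id")

  # ---- stage: preprocess ----
  pp <- config$preprocess
  prep <- lapply(cohort$participants, function(p)
    lapply(p$sessions, function(s) preprocess_session(s$trials, pp)))
  flagged <- unlist(lapply(seq_along(prep), function(pi)
    lapply(seq_along(prep[[pi]]), function(si) {
      fl <- prep[[pi]][[si]]$flagged
      if (length(fl)) paste0(part_ids[pi], "/", sessions[si], ":",
                             paste(fl, collapse = "+")) else character(0)
    })))
  features <- lapply(cohort$participants, function(p)
    lapply(p$sessions, function(s) lapply(s$trials, `[[`, "features")))
  fs <- prep[[1]][[1]]$trials[[1]]$fs
  window <- lag_window(config$lag_window[1], config$lag_window[2], fs)

  # ---- stage: band filtering and ground truth ----
  band_names <- names(config$bands)
  band_eeg <- lapply(band_names, function(bn) {
    bl <- config$bands[[bn]]
    lapply(prep, function(p_sess) lapply(p_sess, function(s)
      lapply(s$trials, function(e) {
        e$data <- zero_phase_bandpass(e$data, bl[1],
                                      min(bl[2], e$fs / 2 * 0.99),
                                      order = pp$order, fs = e$fs)
        e
      })))
  })
  names(band_eeg) <- band_names
  # ground truth: per band, session, trial -> grand mean across channels and
  # participants (already band-filtered above, mean of linear filter = filter
  # of mean)
  truth_traces <- lapply(band_names, function(bn) {
    lapply(seq_along(sessions), function(si) {
      n_trials <- length(band_eeg[[bn]][[1]][[si]])
      lapply(seq_len(n_trials), function(ti) {
        traces <- vapply(seq_len(n_part), function(pi)
          colMeans(band_eeg[[bn]][[pi]][[si]][[ti]]$data),
          numeric(ncol(band_eeg[[bn]][[1]][[si]][[ti]]$data)))
        rowMeans(traces)
      })
    })
  })
  names(truth_traces) <- band_names

  fit_model <- function(pi, si, bn, streams, return_weights = FALSE) {
    fl <- lapply(features[[pi]][[si]], model_matrix_from_features,
                 model = streams)
    el <- lapply(band_eeg[[bn]][[pi]][[si]], `[[`, "data")
    tl <- truth_traces[[bn]][[si]]
    cross_validated_fit_predict(fl, el, tl, window,
                                lambda_grid = config$lambda_grid,
                                penalty = config$penalty,
                                return_weights = return_weights)
  }

  # ---- stage: single-feature models (S, F) ----
  scores <- NULL
  topo <- list()
  if (length(config$models_single) > 0) {
    rows <- list()
    for (bn in band_names) for (mn in names(config$models_single)) {
      topo_m <- NULL
      for (pi in seq_len(n_part)) for (si in seq_along(sessions)) {
        sc <- fit_model(pi, si, bn, config$models_single[[mn]])
        rows[[length(rows) + 1]] <-
          data.frame(participant = part_ids[pi], session = sessions[si],
                     band = bn, model = mn, r_mean = sc$r_mean)
        if (is.null(topo_m))
          topo_m <- array(NA_real_, c(n_part, length(sessions),
                                      length(sc$r_channels)))
        topo_m[pi, si, ] <- sc$r_channels
      }
      topo[[paste(bn, mn, sep = "_")]] <- topo_m
    }
    scores <- do.call(rbind, rows)
  }

  stats_rows <- list()
  add_stat <- function(label, res) {
    stats_rows[[length(stats_rows) + 1]] <<-
      data.frame(label = label, test = res$test, statistic = res$statistic,
                 df1 = res$df[1], df2 = ifelse(length(res$df) > 1,
                                               res$df[2], NA),
                 p_raw = res$p, p_fdr = NA_real_,
                 effect_size = res$effect_size, correction = res$correction,
                 screen = if (!is.null(res$details$screen))
                   res$details$screen else NA_character_)
  }

  # ---- stage: age effects on single-model scores ----
  sig_F_bands <- character(0)
  if (!is.null(scores) && length(sessions) >= 2 && n_part >= 3) {
    for (bn in band_names) for (mn in names(config$models_single)) {
      m <- matrix(NA_real_, n_part, length(sessions))
      for (si in seq_along(sessions))
        m[, si] <- scores$r_mean[scores$band == bn & scores$model == mn &
                                   scores$session == sessions[si]]
      res <- screened_group_test(m, config$alpha)
      add_stat(paste0("age_effect_TRF_", mn, "_", bn), res)
      if (mn == "F" && res$p < config$alpha)
        sig_F_bands <- c(sig_F_bands, bn)
    }
  }

  # ---- stage: prediction gain (FS-S) ----
  # conditional flow: only bands with a significant TRF_F age effect carry
  # the gain analysis, unless an explicit override is configured
  gain_bands <- if (!is.null(config$gain_bands)) {
    intersect(config$gain_bands, band_names)
  } else if (isTRUE(config$gain_band_selection) &&
             length(config$models_single) > 0 &&
             length(sessions) >= 2) sig_F_bands else band_names
  gains <- NULL
  if (length(gain_bands) > 0) {
    grow <- list()
    for (bn in gain_bands) for (pi in seq_len(n_part))
      for (si in seq_along(sessions)) {
        full <- fit_model(pi, si, bn, config$models_gain$full)
        red <- fit_model(pi, si, bn, config$models_gain$reduced)
        grow[[length(grow) + 1]] <-
          data.frame(participant = part_ids[pi], session = sessions[si],
                     band = bn, gain = prediction_gain(full, red))
      }
    gains <- do.call(rbind, grow)

    # one-sample Wilcoxon per band/session + paired contrasts, joint FDR
    wrow <- list()
    for (bn in gain_bands) {
      gm <- matrix(NA_real_, n_part, length(sessions))
      for (si in seq_along(sessions))
        gm[, si] <- gains$gain[gains$band == bn &
                                 gains$session == sessions[si]]
      if (n_part >= 3 && length(sessions) >= 2) {
        add_stat(paste0("age_effect_gain_", bn), screened_group_test(gm,
                                                                     config$alpha))
      }
      if (n_part >= 3) for (si in seq_along(sessions)) {
        res <- wilcoxon_signed_rank(gm[, si])
        wrow[[length(wrow) + 1]] <-
          list(label = paste0("gain_vs_zero_", bn, "_", sessions[si]),
               res = res)
      }
      if (n_part >= 3 && length(sessions) >= 2)
        for (si in 2:length(sessions)) for (sj in seq_len(si - 1)) {
          res <- wilcoxon_signed_rank(gm[, si], gm[, sj])
          wrow[[length(wrow) + 1]] <-
            list(label = paste0("gain_contrast_", bn, "_", sessions[si],
                                "_vs_", sessions[sj]), res = res)
        }
    }
    if (length(wrow) > 0) {
      p_fam <- fdr_bh(vapply(wrow, function(w) w$res$p, numeric(1)))
      for (i in seq_along(wrow)) {
        add_stat(wrow[[i]]$label, wrow[[i]]$res)
        stats_rows[[length(stats_rows)]]$p_fdr <- p_fam[i]
      }
    }
  }

  # ---- stage: topography bootstrap vs reference group ----
  topo_rows <- NULL
  if (length(topo) > 0 && length(sessions) >= 2 && n_part >= 3) {
    bs <- config$bootstrap
    ref_si <- length(sessions)
    trows <- list()
    for (tn in names(topo)) {
      ref_map <- colMeans(topo[[tn]][, ref_si, ])
      for (si in seq_len(length(sessions) - 1)) {
        res <- bootstrap_topography_similarity(
          topo[[tn]][, si, ], ref_map,
          group_size = min(bs$group_size, n_part),
          iterations = bs$iterations,
          seed = derive_seed(config$seed, paste0("boot/", tn, "/", si)))
        trows[[length(trows) + 1]] <-
          data.frame(model_band = tn, session = sessions[si],
                     reference = sessions[ref_si], mean_r = res$mean_r)
      }
    }
    topo_rows <- do.call(rbind, trows)
  }

  # ---- stage: first-word ERP SNR control ----
  snr_tbl <- NULL
  if (!is.null(config$snr)) {
    srow <- list()
    for (pi in seq_len(n_part)) for (si in seq_along(sessions)) {
      vals <- vapply(prep[[pi]][[si]]$trials, function(e)
        tryCatch(snr_first_word(e, config$snr$onset, config$snr$pre_window,
                                config$snr$post_window),
                 error = function(err) NA_real_), numeric(1))
      srow[[length(srow) + 1]] <-
        data.frame(participant = part_ids[pi], session = sessions[si],
                   snr = mean(vals, na.rm = TRUE))
    }
    snr_tbl <- do.call(rbind, srow)
    if (length(sessions) >= 2 && n_part >= 3) {
      sm <- matrix(snr_tbl$snr, n_part, length(sessions), byrow = TRUE)
      add_stat("snr_control", friedman_kendall(sm))
    }
  }

  stats_tbl <- if (length(stats_rows) > 0) do.call(rbind, stats_rows) else
    data.frame()

  provenance <- list(
    package_version = as.character(utils::packageVersion("rhymetrf")),
    seed = config$seed,
    config_hash = derive_seed(0, jsonlite::toJSON(
      config[setdiff(names(config), "paths")], auto_unbox = TRUE,
      force = TRUE)),
    n_participants = n_part, sessions = sessions,
    bands = config$bands, lambda_grid = config$lambda_grid,
    lag_window = config$lag_window, penalty = config$penalty,
    gain_bands = gain_bands, flagged_channels = flagged)

  structure(list(scores = scores, gains = gains, stats = stats_tbl,
                 topography = topo, topography_similarity = topo_rows,
                 snr = snr_tbl, provenance = provenance),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n")
  if (!is.null(x$scores))
    cat(sprintf("  scores: %d rows (%s)\n", nrow(x$scores),
                paste(unique(x$scores$model), collapse = ", ")))
  if (!is.null(x$gains))
    cat(sprintf("  gains: %d rows over bands %s\n", nrow(x$gains),
                paste(unique(x$gains$band), collapse = ", ")))
  cat(sprintf("  stats: %d tests\n",
              if (is.null(x$stats)) 0 else nrow(x$stats)))
  invisible(x)
}

#' Export a results bundle to delimited tables and a JSON summary
#'
#' Writes `scores.csv`, `gains.csv`, `stats.csv`, `snr.csv`,
#' `topography_similarity.csv` (as available), `stats.json` and a
#' `provenance.txt` log. Re-exporting the same bundle yields byte-identical
#' files.
#'
#' @param bundle a `results_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_report <- function(bundle, dir) {
  abort_if(!inherits(bundle, "results_bundle"), "not a results_bundle")
  abort_if(is.null(bundle$stats) && is.null(bundle$scores) &&
             is.null(bundle$gains), "empty bundle")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0)) return()
    p <- file.path(dir, name)
    utils::write.csv(format(df, digits = 15, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$scores, "scores.csv")
  wr(bundle$gains, "gains.csv")
  wr(bundle$stats, "stats.csv")
  wr(bundle$snr, "snr.csv")
  wr(bundle$topography_similarity, "topography_similarity.csv")
  jp <- file.path(dir, "stats.json")
  jsonlite::write_json(list(stats = bundle$stats,
                            provenance = bundle$provenance), jp,
                       auto_unbox = TRUE, digits = 15, pretty = TRUE)
  paths <- c(paths, jp)
  pp <- file.path(dir, "provenance.txt")
  writeLines(c("rhymetrf run provenance",
               paste0("package_version: ",
                      bundle$provenance$package_version),
               paste0("seed: ", bundle$provenance$seed),
               paste0("config_hash: ", bundle$provenance$config_hash),
               paste0("n_participants: ", bundle$provenance$n_participants),
               paste0("sessions: ", paste(bundle$provenance$sessions,
                                          collapse = ", ")),
               paste0("lag_window_s: ", paste(bundle$provenance$lag_window,
                                              collapse = " .. ")),
               paste0("lambda_grid: ", paste(bundle$provenance$lambda_grid,
                                             collapse = ", ")),
               paste0("penalty: ", bundle$provenance$penalty),
               paste0("gain_bands: ", paste(bundle$provenance$gain_bands,
                                            collapse = ", ")),
               paste0("flagged_channels: ",
                      paste(unlist(bundle$provenance$flagged_channels),
                            collapse = "; "))), pp)
  paths <- c(paths, pp)
  invisible(paths)
}

#' Write a cohort dataset to a fixture directory tree
#'
#' Same plain-text containers the real-data path reads: per
#' participant/session/trial a features container and one EEG container per
#' repetition, plus the montage table. The hidden simulation truth is never
#' part of this tree.
#'
#' @param cohort the `data` element of [simulate_longitudinal_cohort()].
#' @param dir output directory.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$montage, file.path(dir, "montage.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(sessions = cohort$sessions, fs = cohort$fs,
                            layout = cohort$layout),
                       file.path(dir, "cohort.json"), auto_unbox = TRUE)
  for (p in cohort$participants) {
    for (s in p$sessions) {
      base <- file.path(dir, p$participant_id, s$session)
      for (ti in seq_along(s$trials)) {
        tr <- s$trials[[ti]]
        td <- file.path(base, paste0("trial_", ti))
        write_features_dir(tr$features, file.path(td, "stim"))
        for (ri in seq_along(tr$repetitions)) {
          e <- tr$repetitions[[ri]]
          e$montage <- NULL            # stored once at cohort level
          write_eeg_dir(e, file.path(td, paste0("rep_", ri)))
        }
      }
    }
  }
  invisible(dir)
}

#' Read a cohort dataset from a fixture directory tree
#'
#' @param dir directory written by [write_cohort_dir()] (or arranged the
#'   same way from real recordings).
#' @return a cohort `data` list as produced by the simulator.
#' @export
read_cohort_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  montage <- utils::read.csv(file.path(dir, "montage.csv"))
  pdirs <- sort(list.dirs(dir, recursive = FALSE))
  participants <- lapply(pdirs, function(pd) {
    sessions <- lapply(meta$sessions, function(ses) {
      sd <- file.path(pd, ses)
      tdirs <- list.dirs(sd, recursive = FALSE)
      tdirs <- tdirs[order(as.integer(sub(".*trial_", "", tdirs)))]
      trials <- lapply(tdirs, function(td) {
        ft <- read_features_dir(file.path(td, "stim"))[[1]]
        rdirs <- sort(list.dirs(td, recursive = FALSE))
        rdirs <- rdirs[grepl("rep_", basename(rdirs))]
        reps <- lapply(rdirs, function(rd) {
          e <- read_eeg_dir(rd)
          e$montage <- montage
          e
        })
        list(features = ft, repetitions = reps)
      })
      list(session = ses, trials = trials)
    })
    list(participant_id = basename(pd), sessions = sessions)
  })
  list(participants = participants, montage = montage,
       layout = meta$layout, sessions = meta$sessions, fs = meta$fs,
       config = NULL)
}
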