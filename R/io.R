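# Readers and writers for the external formats the pipeline consumes:
# Praat TextGrid alignments, PCM WAV audio, luminance tables, and the
# plain-text directory containers used for stimulus features and EEG.

#' Parse a Praat TextGrid interval tier into phoneme alignments
#'
#' Reads the long ("ooTextFile") TextGrid format. Only labelled intervals
#' are returned (empty labels mark silence); output is time-sorted.
#'
#' @param path TextGrid file path.
#' @param tier tier name to read; by default the first interval tier whose
#'   name contains "phon" (case-insensitive), else the first interval tier.
#' @return data.frame with columns `label`, `onset`, `offset`.
#' @export
parse_textgrid <- function(path, tier = NULL) {
  abort_if(!file.exists(path), paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  abort_if(length(lines) == 0 || !any(grepl("TextGrid", lines)),
           paste0(path, ": not a TextGrid (line 1)"))

  num_after <- function(i, key) {
    s <- sub(paste0(".*", key, "\\s*=\\s*"), "", lines[i])
    m <- regmatches(s, regexpr("[-0-9.eE+]+", s))
    if (length(m) == 0 || is.na(suppressWarnings(as.numeric(m))))
      stop(path, ": cannot parse '", key, "' at line ", i, call. = FALSE)
    as.numeric(m)
  }
  str_after <- function(i) {
    m <- regmatches(lines[i], regexpr('"[^"]*"', lines[i]))
    if (length(m) == 0) stop(path, ": cannot parse quoted string at line ", i,
                             call. = FALSE)
    gsub('"', "", m)
  }

  item_starts <- grep("^\\s*item\\s*\\[[0-9]+\\]", lines)
  abort_if(length(item_starts) == 0, paste0(path, ": no tiers found"))
  tiers <- lapply(seq_along(item_starts), function(j) {
    from <- item_starts[j]
    to <- if (j < length(item_starts)) item_starts[j + 1] - 1 else length(lines)
    block <- from:to
    cls_i <- block[grep("class\\s*=", lines[block])[1]]
    name_i <- block[grep("name\\s*=", lines[block])[1]]
    list(from = from, to = to,
         class = if (!is.na(cls_i)) str_after(cls_i) else NA_character_,
         name = if (!is.na(name_i)) str_after(name_i) else NA_character_)
  })
  interval_tiers <- Filter(function(t) identical(t$class, "IntervalTier"), tiers)
  abort_if(length(interval_tiers) == 0,
           paste0(path, ": no IntervalTier present"))
  pick <- if (!is.null(tier)) {
    Filter(function(t) identical(t$name, tier), interval_tiers)
  } else {
    ph <- Filter(function(t) grepl("phon", t$name, ignore.case = TRUE),
                 interval_tiers)
    if (length(ph) > 0) ph else interval_tiers
  }
  abort_if(length(pick) == 0,
           paste0(path, ": no interval tier named '", tier, "'"))
  t <- pick[[1]]

  block <- t$from:t$to
  iv_starts <- block[grep("intervals\\s*\\[[0-9]+\\]", lines[block])]
  out <- lapply(iv_starts, function(i) {
    xmin_i <- i + grep("xmin\\s*=", lines[(i + 1):min(i + 4, t$to)])[1]
    xmax_i <- i + grep("xmax\\s*=", lines[(i + 1):min(i + 4, t$to)])[1]
    text_i <- i + grep("text\\s*=", lines[(i + 1):min(i + 4, t$to)])[1]
    if (any(is.na(c(xmin_i, xmax_i, text_i))))
      stop(path, ": truncated interval at line ", i, call. = FALSE)
    data.frame(label = str_after(text_i),
               onset = num_after(xmin_i, "xmin"),
               offset = num_after(xmax_i, "xmax"))
  })
  out <- do.call(rbind, out)
  out <- out[nzchar(trimws(out$label)), , drop = FALSE]
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  validate_alignments(out)
}

#' Read a PCM WAV file (mono, or first channel)
#'
#' Minimal RIFF/WAVE reader for uncompressed 8/16/32-bit integer PCM.
#' Samples are scaled to `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric vector) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  abort_if(!file.exists(path), paste("no such file:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  abort_if(!identical(hdr, "RIFF"), "not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  abort_if(!identical(readChar(con, 4, useBytes = TRUE), "WAVE"),
           "not a WAVE file")
  fs <- NULL; bits <- NULL; n_ch <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", sz / 2, 2, endian = "little",
                     signed = FALSE)
      abort_if(fmt[1] != 1, "only uncompressed PCM supported")
      n_ch <- fmt[2]
      fs <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
    } else if (identical(id, "data")) {
      abort_if(is.null(bits), "malformed WAV: data before fmt")
      bytes <- bits / 8
      raw <- readBin(con, "integer", sz / bytes, bytes, endian = "little",
                     signed = bits > 8)
      samples <- raw / (2^(bits - 1))
      if (bits == 8) samples <- (raw - 128) / 128
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  abort_if(is.null(samples), "malformed WAV: no data chunk")
  if (n_ch > 1) samples <- samples[seq(1, length(samples), by = n_ch)]
  list(samples = samples, fs = fs)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in `[-1, 1]`.
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @export
write_wav <- function(samples, fs, path) {
  x <- as.integer(pmax(-1, pmin(1, samples)) * 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")          # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little") # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")         # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a per-frame luminance table
#'
#' Plain delimited numeric table; the first numeric column is used.
#'
#' @param path file path.
#' @return numeric vector of per-frame luminance values.
#' @export
read_luminance <- function(path) {
  tab <- utils::read.table(path, header = FALSE)
  num <- tab[, vapply(tab, is.numeric, logical(1)), drop = FALSE]
  abort_if(ncol(num) == 0, "no numeric column in luminance table")
  num[[1]]
}

# ---- directory containers -------------------------------------------------
# Plain-text equivalents of a per-trial HDF5 layout: one subdirectory per
# trial holding CSV matrices plus a JSON metadata sidecar.

write_matrix_csv <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Write stimulus features to a directory container
#'
#' One subdirectory per trial with `S.csv`, `D.csv`, `F.csv`, `V.csv` and
#' `meta.json` (fs, trial id). The synthetic generator writes this same
#' container, so downstream stages cannot distinguish synthetic from real
#' inputs.
#'
#' @param features a `stimulus_features` object or list of them.
#' @param dir output directory (created if needed).
#' @export
write_features_dir <- function(features, dir) {
  if (inherits(features, "stimulus_features")) features <- list(features)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ft in features) {
    d <- file.path(dir, paste0("trial_", ft$trial_id))
    dir.create(d, showWarnings = FALSE)
    write_matrix_csv(ft$S, file.path(d, "S.csv"))
    write_matrix_csv(matrix(ft$D, ncol = 1), file.path(d, "D.csv"))
    write_matrix_csv(ft$F, file.path(d, "F.csv"))
    write_matrix_csv(matrix(ft$V, ncol = 1), file.path(d, "V.csv"))
    jsonlite::write_json(list(fs = ft$fs, trial_id = ft$trial_id),
                         file.path(d, "meta.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read stimulus features from a directory container
#'
#' @param dir directory written by [write_features_dir()].
#' @return list of `stimulus_features`, ordered by trial id.
#' @export
read_features_dir <- function(dir) {
  trials <- list.dirs(dir, recursive = FALSE)
  trials <- trials[grepl("trial_", basename(trials))]
  abort_if(length(trials) == 0, paste("no trials under", dir))
  out <- lapply(trials, function(d) {
    meta <- jsonlite::read_json(file.path(d, "meta.json"))
    stimulus_features(S = read_matrix_csv(file.path(d, "S.csv")),
                      D = as.numeric(read_matrix_csv(file.path(d, "D.csv"))),
                      F = {
                        f <- read_matrix_csv(file.path(d, "F.csv"))
                        colnames(f) <- phonetic_feature_names
                        storage.mode(f) <- "integer"
                        f
                      },
                      V = as.numeric(read_matrix_csv(file.path(d, "V.csv"))),
                      fs = meta$fs, trial_id = meta$trial_id)
  })
  out[order(vapply(out, function(f) f$trial_id, numeric(1)))]
}

#' Write an EEG recording to a directory container
#'
#' `data.csv` is channels x time; `meta.json` carries fs, labels and
#' session metadata; an optional montage table is stored alongside.
#'
#' @param eeg an `eeg_recording`.
#' @param dir output directory.
#' @export
write_eeg_dir <- function(eeg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_csv(eeg$data, file.path(dir, "data.csv"))
  meta <- eeg[setdiff(names(eeg), c("data", "montage"))]
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(eeg$montage))
    utils::write.csv(eeg$montage, file.path(dir, "montage.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read an EEG recording from a directory container
#'
#' @param dir directory written by [write_eeg_dir()].
#' @return an `eeg_recording`.
#' @export
read_eeg_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  montage <- if (file.exists(file.path(dir, "montage.csv")))
    utils::read.csv(file.path(dir, "montage.csv")) else NULL
  do.call(eeg_recording,
          c(list(data = read_matrix_csv(file.path(dir, "data.csv")),
                 montage = montage),
            meta[setdiff(names(meta), c("data", "montage"))]))
}
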