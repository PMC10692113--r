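# Phonetic feature inventory and the binary feature regressor matrix F.

#' The 14 articulatory phonetic feature names
#'
#' Binary descriptors of voicing, manner and place of articulation that
#' jointly encode phoneme identity; the columns of the F regressor matrix,
#' in canonical order.
#' @export
phonetic_feature_names <- c(
  "voiced consonant", "unvoiced consonant", "plosive", "fricative",
  "nasal", "strident", "labial", "coronal", "dorsal", "anterior",
  "front", "back", "high", "low"
)

#' Construct and validate a phoneme feature inventory
#'
#' @param table data.frame with a `phoneme` column plus one 0/1 column per
#'   feature in [phonetic_feature_names].
#' @return an object of class `feature_inventory`: a 0/1 matrix with one row
#'   per phoneme (rownames) and the 14 features as columns.
#' @export
feature_inventory <- function(table) {
  abort_if(!is.data.frame(table) || !"phoneme" %in% names(table),
           "inventory table needs a 'phoneme' column")
  missing <- setdiff(phonetic_feature_names, names(table))
  abort_if(length(missing) > 0,
           paste("inventory table lacks feature columns:",
                 paste(missing, collapse = ", ")))
  m <- as.matrix(table[, phonetic_feature_names])
  storage.mode(m) <- "integer"
  rownames(m) <- table$phoneme
  abort_if(anyDuplicated(table$phoneme) > 0, "duplicate phoneme symbols")
  abort_if(!all(m %in% c(0L, 1L)), "feature values must be 0/1")
  abort_if(any(rowSums(m) == 0),
           "every phoneme must map to at least one feature")
  abort_if(any(m[, "voiced consonant"] + m[, "unvoiced consonant"] > 1),
           "a phoneme cannot be both voiced and unvoiced consonant")
  structure(m, class = c("feature_inventory", class(m)))
}

#' Default phoneme inventory
#'
#' Loads the phoneme-to-feature lookup table shipped with the package: an
#' ARPAbet-like British English inventory mapped to the 14 articulatory
#' features. The table is a reconstruction assembled from standard
#' articulatory-phonetics feature conventions (the exact study inventory is
#' not public); it is a plain TSV that users can edit and reload via
#' [feature_inventory()].
#'
#' @return a `feature_inventory`.
#' @export
default_feature_inventory <- function() {
  path <- system.file("extdata", "phoneme_features.tsv", package = "rhymetrf")
  feature_inventory(utils::read.delim(path, check.names = FALSE))
}

#' Map a phoneme symbol to its binary feature vector
#'
#' @param label phoneme symbol present in the inventory.
#' @param inventory a [feature_inventory()].
#' @return named integer 0/1 vector of length 14.
#' @export
#' @examples
#' phoneme_to_features("b", default_feature_inventory())
phoneme_to_features <- function(label, inventory) {
  abort_if(!inherits(inventory, "feature_inventory"),
           "inventory must be a feature_inventory")
  abort_if(!label %in% rownames(inventory),
           paste0("unknown phoneme symbol: '", label, "'"))
  inventory[label, ]
}

#' Validate a phoneme alignment table
#'
#' Alignments are data.frames with columns `label`, `onset`, `offset`
#' (seconds). Within a trial they must be time-sorted and non-overlapping.
#'
#' @param alignments data.frame.
#' @return the validated data.frame (invisibly usable downstream).
#' @export
validate_alignments <- function(alignments) {
  abort_if(!is.data.frame(alignments) ||
             !all(c("label", "onset", "offset") %in% names(alignments)),
           "alignments need columns label/onset/offset")
  if (nrow(alignments) == 0) return(alignments)
  abort_if(any(alignments$onset < 0), "onsets must be >= 0")
  abort_if(any(alignments$offset <= alignments$onset),
           "each offset must exceed its onset")
  abort_if(is.unsorted(alignments$onset),
           "alignments must be time-sorted")
  abort_if(any(utils::head(alignments$offset, -1) >
                 utils::tail(alignments$onset, -1) + 1e-9),
           "alignments must be non-overlapping")
  alignments
}

#' Binary phonetic feature matrix F from phoneme alignments
#'
#' Marks the occurrence of each phoneme from start to finish with unit
#' rectangular pulses on its feature rows, at the analysis rate. Sample
#' indexing is half-open `[round(onset * fs), round(offset * fs))`; a
#' phoneme that rounds to zero duration still occupies one sample.
#' Overlapping pulses combine by logical OR (entries stay binary).
#'
#' @param alignments data.frame of phoneme alignments (label/onset/offset).
#' @param inventory a [feature_inventory()].
#' @param fs_out analysis rate in Hz.
#' @param duration trial duration in seconds.
#' @return `round(duration * fs_out)` x 14 binary matrix with the feature
#'   names as columns.
#' @export
phonetic_feature_matrix <- function(alignments, inventory, fs_out, duration) {
  validate_alignments(alignments)
  n <- round_half_away(duration * fs_out)
  F_mat <- matrix(0L, n, length(phonetic_feature_names),
                  dimnames = list(NULL, phonetic_feature_names))
  if (nrow(alignments) == 0) return(F_mat)
  abort_if(any(alignments$offset > duration + 1e-9),
           "alignment extends beyond trial duration")
  for (i in seq_len(nrow(alignments))) {
    i0 <- round_half_away(alignments$onset[i] * fs_out) + 1L
    i1 <- round_half_away(alignments$offset[i] * fs_out)
    if (i1 < i0) i1 <- i0                       # minimum one sample
    i1 <- min(i1, n)
    i0 <- min(i0, n)
    fv <- phoneme_to_features(alignments$label[i], inventory)
    F_mat[i0:i1, ] <- pmax(F_mat[i0:i1, , drop = FALSE],
                           rep(fv, each = i1 - i0 + 1L))
  }
  F_mat
}
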