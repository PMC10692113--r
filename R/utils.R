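# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding used for all time -> sample-index conversions
#' (base R `round()` rounds half to even, which would make lag windows
#' depend on floating-point parity).
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic components draw their seeds through this mixer so that a
#' single master seed determines every random stream without any reliance on
#' global RNG state ordering. Keys are arbitrary strings (e.g.
#' "participant3/session2/noise").
#'
#' @param master integer master seed.
#' @param key character scalar naming the stream.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "cohort/participant1")
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  # FNV-1a style string hash folded with the master seed, kept below 2^31
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(paste0(key, ":", as.integer(master)))) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646)
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never
#' perturbs global random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}
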