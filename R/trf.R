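# Multivariate forward TRF estimation: lagged design matrices, Tikhonov/ridge
# solves, nested leave-one-trial-out cross-validation with lambda tuning, and
# prediction correlation against a shared ground-truth EEG trace.
#
# The cross-validation engine precomputes per-trial Gram matrices (X'X, X'Y)
# once; any training fold's normal equations are then sums/differences of
# per-trial Grams, which makes nested lambda tuning affordable.

#' Lag window for a TRF model
#'
#' Converts a latency window in seconds to inclusive integer sample lags.
#' Endpoints are rounded half-away-from-zero. Negative lags (stimulus after
#' response) are acausal and serve to absorb regression edge artefacts.
#'
#' @param tmin,tmax window in seconds (`tmin < tmax`; `tmin` may be negative).
#' @param fs sampling rate in Hz.
#' @return object of class `lag_window` with `lags` (integer samples),
#'   `tmin`, `tmax`, `fs`.
#' @export
#' @examples
#' length(lag_window(-0.1, 0.5, 50)$lags)  # 31 lags
lag_window <- function(tmin, tmax, fs) {
  abort_if(tmin >= tmax, "tmin must be < tmax")
  lags <- seq.int(round_half_away(tmin * fs), round_half_away(tmax * fs))
  structure(list(lags = lags, tmin = tmin, tmax = tmax, fs = fs),
            class = "lag_window")
}

#' Build the lagged design matrix
#'
#' One column block per feature, one column per lag within a block
#' (feature-major ordering). A response sample at time `t` is modelled from
#' the stimulus at `t - lag`; samples shifted outside the trial are
#' zero-padded.
#'
#' @param features time x F numeric matrix of stimulus streams.
#' @param window a [lag_window()].
#' @return time x (F * L) matrix, L the number of lags.
#' @export
lag_design_matrix <- function(features, window) {
  features <- as.matrix(features)
  abort_if(nrow(features) == 0 || ncol(features) == 0, "empty features")
  abort_if(any(!is.finite(features)), "features must be finite")
  n <- nrow(features)
  nf <- ncol(features)
  lags <- window$lags
  L <- length(lags)
  X <- matrix(0, n, nf * L)
  for (li in seq_along(lags)) {
    l <- lags[li]
    src <- seq_len(n) - l
    ok <- src >= 1 & src <= n
    cols <- (seq_len(nf) - 1L) * L + li
    X[ok, cols] <- features[src[ok], , drop = FALSE]
  }
  X
}

# Quadratic penalty matrix over the lagged design columns (intercept
# excluded). "identity" is per-coefficient ridge; "derivative" penalises the
# second difference of each feature's lag profile (banded, per-feature
# blocks), favouring smooth TRFs.
penalty_matrix <- function(n_features, n_lags, kind = c("identity",
                                                        "derivative")) {
  kind <- match.arg(kind)
  p <- n_features * n_lags
  if (kind == "identity") return(diag(p))
  if (n_lags < 3) return(diag(p))
  D2 <- diff(diag(n_lags), differences = 2)
  block <- crossprod(D2) + 1e-6 * diag(n_lags)  # keep strictly positive definite
  M <- matrix(0, p, p)
  for (f in seq_len(n_features)) {
    idx <- (f - 1L) * n_lags + seq_len(n_lags)
    M[idx, idx] <- block
  }
  M
}

#' Ridge / Tikhonov solve of the TRF normal equations
#'
#' Solves `w = (X'X + lambda * M)^-1 X'Y` with an unpenalised intercept.
#' `M` is the identity (per-coefficient ridge) or a banded second-difference
#' penalty over each feature's lags (smoothness prior).
#'
#' @param X time x p lagged design matrix (no intercept column).
#' @param Y time x channels response matrix (a vector is treated as one
#'   channel).
#' @param lambda regularisation scalar, >= 0.
#' @param penalty `"identity"` or `"derivative"`.
#' @param n_lags lags per feature block (required for the derivative
#'   penalty; defaults to treating all columns as one block).
#' @return list with `w` (p x channels) and `bias` (per channel).
#' @export
ridge_solve <- function(X, Y, lambda, penalty = c("identity", "derivative"),
                        n_lags = NULL) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X); Y <- as.matrix(Y)
  abort_if(nrow(X) != nrow(Y), "X and Y must have the same number of rows")
  abort_if(lambda < 0, "lambda must be >= 0")
  p <- ncol(X)
  if (is.null(n_lags)) n_lags <- p
  n_features <- p / n_lags
  abort_if(n_features != round(n_features),
           "ncol(X) must be a multiple of n_lags")
  M <- penalty_matrix(n_features, n_lags, penalty)
  Xa <- cbind(1, X)
  A <- crossprod(Xa)
  A[-1, -1] <- A[-1, -1] + lambda * M
  b <- crossprod(Xa, Y)
  w_all <- tryCatch(solve(A, b), error = function(e)
    stop("singular system; use lambda > 0", call. = FALSE))
  list(w = w_all[-1, , drop = FALSE], bias = w_all[1, ])
}

#' Per-channel Pearson prediction correlation
#'
#' Correlates each predicted channel with the one shared ground-truth trace.
#'
#' @param predicted channels x time matrix (or a vector).
#' @param truth numeric vector of the same length.
#' @return numeric vector of per-channel r.
#' @export
prediction_correlation <- function(predicted, truth) {
  if (is.vector(predicted)) predicted <- matrix(predicted, nrow = 1)
  abort_if(ncol(predicted) != length(truth),
           "predicted and truth must have equal lengths")
  abort_if(stats::sd(truth) == 0, "ground-truth trace has zero variance")
  sds <- apply(predicted, 1, stats::sd)
  abort_if(any(sds == 0), "a predicted channel has zero variance")
  as.numeric(stats::cor(t(predicted), truth))
}

# ---- internal CV engine ---------------------------------------------------

# Precompute per-trial design matrices and Gram blocks for a list of trials.
# features_list: list of T_i x F matrices; eeg_list: list of C x T_i.
trf_precompute <- function(features_list, eeg_list, window) {
  nf <- ncol(features_list[[1]])
  L <- length(window$lags)
  lapply(seq_along(features_list), function(i) {
    X <- cbind(1, lag_design_matrix(features_list[[i]], window))
    Yt <- t(eeg_list[[i]])
    f <- features_list[[i]]
    list(X = X, Y = Yt, G = crossprod(X), C = crossprod(X, Yt),
         s1 = colSums(f), s2 = colSums(f^2), n = nrow(f))
  })
}

# Column scaling vector (design columns incl. intercept) from training-fold
# per-stream SDs: each original feature column is scaled to unit variance,
# identically across its lag copies. Zero-variance streams are left alone.
train_scale <- function(pre, train_idx, n_lags) {
  s1 <- Reduce(`+`, lapply(pre[train_idx], `[[`, "s1"))
  s2 <- Reduce(`+`, lapply(pre[train_idx], `[[`, "s2"))
  n <- sum(vapply(pre[train_idx], `[[`, numeric(1), "n"))
  v <- s2 / n - (s1 / n)^2
  sds <- sqrt(pmax(v, 0))
  sds[sds < 1e-12] <- 1
  c(1, rep(1 / sds, each = n_lags))
}

# Solve the scaled, penalised normal equations from summed Gram blocks
# (Cholesky; the system is symmetric positive definite for lambda > 0).
# Returns the effective (unscaled-space) weight matrix incl. intercept row.
gram_solve <- function(G, C, d, lambda, M) {
  A <- G * tcrossprod(d)
  A[-1, -1] <- A[-1, -1] + lambda * M
  b <- C * d
  w_s <- tryCatch({
    R <- chol(A)
    backsolve(R, backsolve(R, b, transpose = TRUE))
  }, error = function(e) stop("singular system; use lambda > 0",
                              call. = FALSE))
  w_s * d
}

mean_pred_r <- function(w_eff, X, truth) {
  pred <- X %*% w_eff
  psd <- apply(pred, 2, stats::sd)
  if (stats::sd(truth) == 0 || all(psd == 0)) return(0)
  r <- suppressWarnings(as.numeric(stats::cor(pred, truth)))
  mean(r, na.rm = TRUE)
}

#' Tune the Tikhonov regularisation parameter
#'
#' Exhaustive search over a logarithmic grid: for each candidate lambda the
#' mean leave-one-trial-out prediction correlation (averaged over channels
#' and folds) is computed on the supplied training trials; the maximiser is
#' returned, with ties resolved toward the smaller lambda.
#'
#' @param features_list list of time x F stimulus matrices (one per trial).
#' @param eeg_list list of channels x time EEG matrices.
#' @param truth_list list of ground-truth trace segments (one per trial).
#' @param window a [lag_window()].
#' @param lambda_grid candidate lambdas; default powers of 10 from 1e-2 to
#'   1e6.
#' @param penalty `"identity"` or `"derivative"`.
#' @return the selected lambda (scalar).
#' @export
tune_lambda <- function(features_list, eeg_list, truth_list, window,
                        lambda_grid = 10^seq(-2, 6), penalty = "identity") {
  abort_if(length(features_list) < 2, "need at least 2 training trials")
  abort_if(length(lambda_grid) == 0, "empty lambda grid")
  pre <- trf_precompute(features_list, eeg_list, window)
  sel <- tune_lambda_pre(pre, truth_list, seq_along(pre), window,
                         sort(lambda_grid), penalty)
  sel$lambda
}

tune_lambda_pre <- function(pre, truth_list, train_idx, window, grid,
                            penalty, M = NULL) {
  n_lags <- length(window$lags)
  nf <- (ncol(pre[[1]]$G) - 1L) / n_lags
  if (is.null(M)) M <- penalty_matrix(nf, n_lags, penalty)
  if (length(grid) == 1L)
    return(list(lambda = grid, scores = NA_real_))
  if (length(train_idx) == 1L) {
    # single training trial: inner validation on its second half
    j <- train_idx
    half <- floor(nrow(pre[[j]]$X) / 2)
    X1 <- pre[[j]]$X[seq_len(half), , drop = FALSE]
    X2 <- pre[[j]]$X[(half + 1):nrow(pre[[j]]$X), , drop = FALSE]
    Y1 <- pre[[j]]$Y[seq_len(half), , drop = FALSE]
    G1 <- crossprod(X1)
    C1 <- crossprod(X1, Y1)
    sds <- apply(X1[, -1, drop = FALSE], 2, stats::sd)
    sds[sds < 1e-12] <- 1
    d <- c(1, 1 / sds)
    tr2 <- truth_list[[j]][(half + 1):nrow(pre[[j]]$X)]
    scores <- vapply(grid, function(l)
      mean_pred_r(gram_solve(G1, C1, d, l, M), X2, tr2), numeric(1))
    abort_if(all(is.na(scores)), "all inner-fold scores are NaN")
    return(list(lambda = grid[which.max(scores)], scores = scores))
  }
  G_tr <- Reduce(`+`, lapply(pre[train_idx], `[[`, "G"))
  C_tr <- Reduce(`+`, lapply(pre[train_idx], `[[`, "C"))
  scores <- matrix(NA_real_, length(train_idx), length(grid))
  for (jj in seq_along(train_idx)) {
    j <- train_idx[jj]
    inner <- setdiff(train_idx, j)
    d <- train_scale(pre, inner, n_lags)
    G_in <- G_tr - pre[[j]]$G
    C_in <- C_tr - pre[[j]]$C
    for (li in seq_along(grid)) {
      w_eff <- gram_solve(G_in, C_in, d, grid[li], M)
      scores[jj, li] <- mean_pred_r(w_eff, pre[[j]]$X, truth_list[[j]])
    }
  }
  mean_scores <- colMeans(scores)
  abort_if(all(is.na(mean_scores)), "all inner-fold scores are NaN")
  list(lambda = grid[which.max(mean_scores)], scores = mean_scores)
}

#' Leave-one-trial-out cross-validated TRF fit and prediction
#'
#' For each fold, the regularisation parameter is tuned by an inner
#' leave-one-out search on the training trials only, the TRF is fit on the
#' training trials, the held-out trial is predicted, and each predicted
#' channel is correlated with the ground-truth trace segment of that trial.
#' Feature streams are scaled to unit variance using training-fold
#' statistics only.
#'
#' @inheritParams tune_lambda
#' @param return_weights if `TRUE`, also return the fold-averaged TRF
#'   weight tensor (feature x lag x channel, in original feature units).
#' @return object of class `prediction_score`: list with `r_channels`
#'   (per-channel r averaged over folds), `r_mean`, `lambdas` (per fold),
#'   `n_folds`, and optionally `weights`.
#' @export
cross_validated_fit_predict <- function(features_list, eeg_list, truth_list,
                                        window,
                                        lambda_grid = 10^seq(-2, 6),
                                        penalty = "identity",
                                        return_weights = FALSE) {
  k <- length(features_list)
  abort_if(k < 2, "need at least 2 trials")
  abort_if(length(eeg_list) != k || length(truth_list) != k,
           "features, EEG and truth must have one element per trial")
  for (i in seq_len(k))
    abort_if(nrow(features_list[[i]]) != ncol(eeg_list[[i]]) ||
               nrow(features_list[[i]]) != length(truth_list[[i]]),
             "per-trial lengths of features, EEG and truth must match")
  grid <- sort(lambda_grid)
  pre <- trf_precompute(features_list, eeg_list, window)
  n_lags <- length(window$lags)
  nf <- ncol(features_list[[1]])
  n_ch <- nrow(eeg_list[[1]])
  M <- penalty_matrix(nf, n_lags, penalty)
  G_tot <- Reduce(`+`, lapply(pre, `[[`, "G"))
  C_tot <- Reduce(`+`, lapply(pre, `[[`, "C"))

  r_folds <- matrix(NA_real_, k, n_ch)
  lambdas <- numeric(k)
  W_sum <- 0
  for (i in seq_len(k)) {
    train_idx <- setdiff(seq_len(k), i)
    lam <- tune_lambda_pre(pre, truth_list, train_idx, window, grid,
                           penalty, M)$lambda
    lambdas[i] <- lam
    d <- train_scale(pre, train_idx, n_lags)
    w_eff <- gram_solve(G_tot - pre[[i]]$G, C_tot - pre[[i]]$C, d, lam, M)
    pred <- pre[[i]]$X %*% w_eff
    abort_if(nrow(pred) != length(truth_list[[i]]),
             "prediction / ground-truth length mismatch")
    r_folds[i, ] <- prediction_correlation(t(pred), truth_list[[i]])
    if (return_weights) W_sum <- W_sum + w_eff[-1, , drop = FALSE]
  }
  r_channels <- colMeans(r_folds)
  out <- list(r_channels = r_channels, r_mean = mean(r_channels),
              lambdas = lambdas, n_folds = k)
  if (return_weights) {
    W <- W_sum / k
    out$weights <- aperm(array(W, dim = c(n_lags, nf, n_ch)), c(2, 1, 3))
    dimnames(out$weights) <- list(colnames(features_list[[1]]),
                                  NULL, NULL)
    out$lags <- window$lags
  }
  class(out) <- "prediction_score"
  out
}

#' @export
print.prediction_score <- function(x, ...) {
  cat(sprintf(
    "<prediction_score> mean r = %.4f over %d channels, %d folds (lambda in [%g, %g])\n",
    x$r_mean, length(x$r_channels), x$n_folds, min(x$lambdas),
    max(x$lambdas)))
  invisible(x)
}

#' Fit a single TRF model on all trials (no cross-validation)
#'
#' Used for weight inspection and parameter-recovery checks.
#'
#' @inheritParams tune_lambda
#' @param lambda regularisation scalar.
#' @return object of class `trf_model` with `weights` (feature x lag x
#'   channel, original feature units), `bias`, `lambda`, `lags`, `fs`.
#' @export
trf_fit <- function(features_list, eeg_list, window, lambda,
                    penalty = "identity") {
  pre <- trf_precompute(features_list, eeg_list, window)
  n_lags <- length(window$lags)
  nf <- ncol(features_list[[1]])
  n_ch <- nrow(eeg_list[[1]])
  M <- penalty_matrix(nf, n_lags, penalty)
  G <- Reduce(`+`, lapply(pre, `[[`, "G"))
  C <- Reduce(`+`, lapply(pre, `[[`, "C"))
  d <- train_scale(pre, seq_along(pre), n_lags)
  w_eff <- gram_solve(G, C, d, lambda, M)
  W <- aperm(array(w_eff[-1, , drop = FALSE], dim = c(n_lags, nf, n_ch)),
             c(2, 1, 3))
  dimnames(W) <- list(colnames(features_list[[1]]), NULL, NULL)
  structure(list(weights = W, bias = w_eff[1, ], lambda = lambda,
                 lags = window$lags, fs = window$fs, penalty = penalty),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf(
    "<trf_model> %d features x %d lags x %d channels, lambda = %g, %s penalty\n",
    d[1], d[2], d[3], x$lambda, x$penalty))
  invisible(x)
}

#' EEG prediction gain of a full over a reduced model (FS-S)
#'
#' The across-channel mean prediction correlation of the acoustic-phonetic
#' model minus that of the acoustic-only model. A positive gain indicates
#' phonetic-feature encoding beyond what the acoustics explain.
#'
#' @param full,reduced `prediction_score` objects for the same
#'   participant/band (full: acoustic + phonetic regressors; reduced:
#'   acoustic only).
#' @return scalar gain.
#' @export
prediction_gain <- function(full, reduced) {
  abort_if(!inherits(full, "prediction_score") ||
             !inherits(reduced, "prediction_score"),
           "inputs must be prediction_score objects")
  abort_if(length(full$r_channels) != length(reduced$r_channels),
           "mismatched channel sets")
  for (key in c("participant", "session", "band"))
    abort_if(!is.null(full[[key]]) && !is.null(reduced[[key]]) &&
               !identical(full[[key]], reduced[[key]]),
             paste("mismatched metadata:", key))
  full$r_mean - reduced$r_mean
}

#' Assemble a model regressor matrix from stimulus features
#'
#' @param ft a [stimulus_features()] object.
#' @param model character vector naming the streams to include, from
#'   `"S"`, `"D"`, `"V"`, `"F"` (order is respected).
#' @return time x F numeric matrix with named columns.
#' @export
model_matrix_from_features <- function(ft, model = c("S", "D", "V", "F")) {
  abort_if(!all(model %in% c("S", "D", "V", "F")),
           "model names must be among S, D, V, F")
  blocks <- lapply(model, function(m) {
    switch(m,
           S = {b <- ft$S; colnames(b) <- paste0("S", seq_len(ncol(b))); b},
           D = matrix(ft$D, ncol = 1, dimnames = list(NULL, "D")),
           V = matrix(ft$V, ncol = 1, dimnames = list(NULL, "V")),
           F = {b <- ft$F * 1.0; b})
  })
  do.call(cbind, blocks)
}
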