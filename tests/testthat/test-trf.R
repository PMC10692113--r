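# TRF core: lag design, ridge solves, lambda tuning, cross-validated
# prediction, gains.

test_that("lag_design_matrix builds the stated lag structure", {
  w <- lag_window(-0.1, 0.5, 50)
  expect_length(w$lags, 31)                  # -5 .. 25 inclusive
  expect_equal(range(w$lags), c(-5, 25))

  # window (0,0): identity on the features
  x <- matrix(rnorm(40), 20, 2)
  w0 <- lag_window(-0.009, 0.009, 50)        # rounds to single zero lag
  expect_equal(lag_design_matrix(x, w0), x, ignore_attr = TRUE)

  # impulse feature: each lag column is the shifted impulse
  imp <- matrix(0, 30, 1); imp[10, 1] <- 1
  wl <- lag_window(-2 / 50, 3 / 50, 50)      # lags -2..3
  X <- lag_design_matrix(imp, wl)
  for (li in seq_along(wl$lags))
    expect_equal(which(X[, li] == 1), 10 + wl$lags[li])

  expect_error(lag_design_matrix(matrix(numeric(0), 0, 2), wl), "empty")
  expect_error(lag_window(0.5, -0.1, 50), "tmin")
})

test_that("ridge_solve matches an independent augmented-least-squares oracle", {
  set.seed(21)
  n <- 60; p <- 8
  X <- matrix(rnorm(n * p), n)
  Y <- cbind(rnorm(n), rnorm(n))
  for (lam in c(0, 1, 100)) {
    fit <- ridge_solve(X, Y, lam)
    # oracle: ridge as augmented least squares via QR (intercept unpenalised)
    Xa <- cbind(1, X)
    Xaug <- rbind(Xa, cbind(0, sqrt(lam) * diag(p)))
    Yaug <- rbind(Y, matrix(0, p, 2))
    w_or <- qr.coef(qr(Xaug), Yaug)
    expect_lt(max(abs(fit$w - w_or[-1, ])), 1e-8)
    expect_lt(max(abs(fit$bias - w_or[1, ])), 1e-8)
  }

  # y = x exactly: unit weight, zero bias
  x1 <- matrix(rnorm(50), 50, 1)
  f <- ridge_solve(x1, x1, 0)
  expect_equal(as.numeric(f$w), 1, tolerance = 1e-10)
  expect_equal(as.numeric(f$bias), 0, tolerance = 1e-10)

  # penalty dominance: ||w|| decreases monotonically in lambda
  norms <- vapply(10^(0:9), function(l)
    sum(ridge_solve(X, Y, l)$w^2), numeric(1))
  expect_true(all(diff(norms) < 0))

  # singular system at lambda = 0
  Xs <- cbind(X, X[, 1])
  expect_error(ridge_solve(Xs, Y, 0), "lambda > 0")
})

test_that("increasing lambda never improves training fit", {
  set.seed(22)
  X <- matrix(rnorm(200 * 10), 200)
  y <- X %*% rnorm(10) + rnorm(200)
  rss <- vapply(10^seq(-2, 6), function(l) {
    f <- ridge_solve(X, y, l)
    sum((y - X %*% f$w - rep(f$bias, 200))^2)
  }, numeric(1))
  expect_true(all(diff(rss) > -1e-8))
})

test_that("prediction_correlation matches the covariance formula and its invariances", {
  set.seed(23)
  P <- matrix(rnorm(300), 3)
  tr <- rnorm(100)
  r <- prediction_correlation(P, tr)
  direct <- apply(P, 1, function(p)
    sum((p - mean(p)) * (tr - mean(tr))) /
      sqrt(sum((p - mean(p))^2) * sum((tr - mean(tr))^2)))
  expect_equal(r, direct, tolerance = 1e-12)

  expect_equal(prediction_correlation(rbind(tr, tr), tr), c(1, 1))
  expect_equal(prediction_correlation(-tr, tr), -1)
  # invariant to affine rescaling of the truth trace
  expect_equal(prediction_correlation(P, 3 * tr + 7), r, tolerance = 1e-12)
  expect_error(prediction_correlation(P, rep(1, 100)), "zero variance")
})

test_that("tune_lambda honours the grid and the bias-variance extremes", {
  set.seed(24)
  fs <- 25
  w <- lag_window(-0.1, 0.4, fs)
  feats <- lapply(1:3, function(i) matrix(rnorm(150 * 2), 150))
  kern <- matrix(rnorm(2 * 11), 2)
  kw <- lag_window(0, 0.4, fs)
  make_eeg <- function(f) t(lag_design_matrix(f, kw) %*% as.numeric(t(kern)))
  eeg_clean <- lapply(feats, make_eeg)
  truth <- lapply(eeg_clean, function(e) as.numeric(e))

  expect_equal(tune_lambda(feats, eeg_clean, truth, w, lambda_grid = 42), 42)

  # noiseless data -> lambda* at/near the grid minimum
  lam_clean <- tune_lambda(feats, eeg_clean, truth, w,
                           lambda_grid = 10^seq(-2, 6, 2))
  expect_lte(lam_clean, 1)

  # pure-noise targets -> lambda* at/near the grid maximum
  eeg_noise <- lapply(feats, function(f) t(as.matrix(rnorm(nrow(f)))))
  truth_n <- lapply(eeg_noise, as.numeric)
  lam_noise <- tune_lambda(feats, eeg_noise, truth_n, w,
                           lambda_grid = 10^seq(-2, 6, 2))
  expect_gte(lam_noise, 1e4)

  expect_error(tune_lambda(feats[1], eeg_clean[1], truth[1], w), "2 training")
})

test_that("cross-validated prediction recovers a noiseless forward model", {
  set.seed(25)
  fs <- 25
  w <- lag_window(-0.1, 0.5, fs)
  kw <- lag_window(0, 0.4, fs)
  nf <- 3; L <- length(kw$lags); n_ch <- 4
  kern <- matrix(rnorm(nf * L), nf)         # same kernel on every channel
  feats <- lapply(1:4, function(i) matrix(rnorm(200 * nf), 200))
  eeg <- lapply(feats, function(f) {
    y <- lag_design_matrix(f, kw) %*% as.numeric(t(kern))
    t(matrix(rep(y, n_ch), ncol = n_ch))
  })
  truth <- lapply(eeg, function(e) colMeans(e))
  sc <- cross_validated_fit_predict(feats, eeg, truth, w,
                                    lambda_grid = 10^c(-2, 0, 2))
  expect_s3_class(sc, "prediction_score")
  expect_equal(sc$n_folds, 4)
  expect_length(sc$r_channels, n_ch)
  expect_gt(sc$r_mean, 0.95)

  # time-shuffled features carry no information: r ~ 0
  feats_shuf <- lapply(feats, function(f) f[sample(nrow(f)), , drop = FALSE])
  sc0 <- cross_validated_fit_predict(feats_shuf, eeg, truth, w,
                                     lambda_grid = 10^c(-2, 0, 2))
  expect_lt(abs(sc0$r_mean), 2 / sqrt(200))

  expect_error(cross_validated_fit_predict(feats[1:2], eeg[1:3],
                                           truth[1:3], w), "per trial")
})

test_that("fitted TRF weights recover generator kernels at reduced data volume", {
  # smoke-level recovery (6 trials x 12 s); the full-strength check at the
  # study's data volume lives in the acceptance suite
  rec <- kernel_recovery_experiment(seed = 31, n_trials = 6, duration = 12,
                                    fs = 25, lambda = 500)
  expect_gt(rec$r_S, 0.7)
  expect_gt(rec$r_F, 0.7)
  expect_s3_class(rec$fit, "trf_model")
})

test_that("prediction_gain subtracts channel-mean correlations with metadata checks", {
  sc <- function(r, extra = list()) {
    structure(c(list(r_channels = r, r_mean = mean(r), lambdas = 1,
                     n_folds = 2), extra), class = "prediction_score")
  }
  expect_equal(prediction_gain(sc(c(0.3, 0.5)), sc(c(0.3, 0.5))), 0)
  expect_equal(prediction_gain(sc(c(0.4, 0.6)), sc(c(0.1, 0.3))), 0.3)
  expect_error(prediction_gain(sc(c(0.4, 0.6)), sc(c(0.1, 0.3, 0.2))),
               "channel")
  expect_error(prediction_gain(sc(0.5, list(band = "delta")),
                               sc(0.4, list(band = "theta"))), "band")
})

test_that("model_matrix_from_features assembles the declared compositions", {
  sim <- simulate_longitudinal_cohort(do.call(
    sim_config, c(tiny_sim_block(n = 1, sessions = "s", gains = 1,
                                 trials = 1, dur = 4), seed = 41)))
  ft <- sim$data$participants[[1]]$sessions[[1]]$trials[[1]]$features
  full <- model_matrix_from_features(ft, c("S", "D", "V", "F"))
  expect_equal(ncol(full), 24)
  expect_equal(colnames(full)[1:8], paste0("S", 1:8))
  red <- model_matrix_from_features(ft, c("S", "D", "V"))
  expect_equal(ncol(red), 10)
  expect_error(model_matrix_from_features(ft, c("S", "Q")), "among")
})
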