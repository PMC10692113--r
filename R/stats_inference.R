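# Repeated-measures statistical battery: Wilcoxon signed-rank, one-way
# rmANOVA with Mauchly screening and Greenhouse-Geisser correction, Friedman
# with Kendall's W, Shapiro-Wilk normality screening, BH-FDR, and the
# bootstrap topography-similarity analysis.

stat_result <- function(test, statistic, df, p, effect_size = NA_real_,
                        correction = "none", details = list()) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 effect_size = effect_size, correction = correction,
                 details = details),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = (%s), p = %.4g%s\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = ", "), x$p,
              if (x$correction != "none")
                paste0(" [", x$correction, "]") else ""))
  invisible(x)
}

#' Two-tailed Wilcoxon signed-rank test
#'
#' One-sample test of symmetry about `mu` (or of paired differences about
#' zero). Zeros are dropped before ranking. For 15 or fewer nonzero
#' differences without ties the p-value is exact (equivalent to enumerating
#' all 2^n sign assignments); otherwise a normal approximation with
#' continuity correction is used.
#'
#' @param x numeric vector (observations, or paired differences when
#'   `mode = "paired-differences"` and `y` is given).
#' @param y optional second sample for the paired mode.
#' @param mu null location, default 0.
#' @param exact_n largest n for the exact path (default 15).
#' @return a `stat_result` with the V statistic.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0, exact_n = 15) {
  d <- if (is.null(y)) x - mu else (x - y) - mu
  d <- d[d != 0]
  abort_if(length(d) < 3, "need at least 3 nonzero differences")
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= exact_n && !ties
  ht <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  stat_result("wilcoxon_signed_rank", unname(ht$statistic), length(d),
              ht$p.value,
              details = list(exact = exact, n_nonzero = length(d)))
}

#' One-way repeated-measures ANOVA
#'
#' Two-way (subject x condition) decomposition: `F = MS_condition /
#' MS_error` with df `(k - 1, (n - 1)(k - 1))`. Mauchly's sphericity test is
#' run for `k > 2`; when it rejects at `alpha`, both df are multiplied by
#' the Greenhouse-Geisser epsilon. Partial eta squared is
#' `SS_cond / (SS_cond + SS_err)`.
#'
#' @param data n subjects x k conditions numeric matrix (complete).
#' @param sphericity_alpha level of the Mauchly screen (default 0.05).
#' @param force_gg apply the Greenhouse-Geisser correction regardless of
#'   the Mauchly outcome.
#' @return a `stat_result` with F, (possibly corrected) df, p, partial eta
#'   squared, and epsilon/Mauchly details.
#' @export
rm_anova_oneway <- function(data, sphericity_alpha = 0.05, force_gg = FALSE) {
  data <- as.matrix(data)
  abort_if(anyNA(data), "missing cells are not supported (no imputation)")
  n <- nrow(data); k <- ncol(data)
  abort_if(n < 3 || k < 2, "need n >= 3 subjects and k >= 2 conditions")
  grand <- mean(data)
  ss_subj <- k * sum((rowMeans(data) - grand)^2)
  ss_cond <- n * sum((colMeans(data) - grand)^2)
  ss_tot <- sum((data - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df_cond <- k - 1
  df_err <- (n - 1) * (k - 1)
  if (ss_cond == 0) {
    F_val <- 0
    eta_p <- 0
  } else {
    F_val <- (ss_cond / df_cond) / (ss_err / df_err)
    eta_p <- ss_cond / (ss_cond + ss_err)
  }

  eps <- 1
  mauchly_p <- NA_real_
  if (k > 2) {
    eps <- tryCatch(greenhouse_geisser_epsilon(data),
                    error = function(e) 1)
    mfit <- stats::lm(data ~ 1)
    mauchly_p <- tryCatch(stats::mauchly.test(mfit, X = ~1)$p.value,
                          error = function(e) NA_real_)
  }
  apply_gg <- force_gg || (!is.na(mauchly_p) && mauchly_p < sphericity_alpha)
  df <- c(df_cond, df_err)
  if (apply_gg) df <- df * eps
  p <- stats::pf(F_val, df[1], df[2], lower.tail = FALSE)
  stat_result("rm_anova_oneway", F_val, df, p, effect_size = eta_p,
              correction = if (apply_gg) "Greenhouse-Geisser" else "none",
              details = list(epsilon = eps, mauchly_p = mauchly_p,
                             ss = c(subject = ss_subj, condition = ss_cond,
                                    error = ss_err, total = ss_tot)))
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor computed from the sample
#' covariance of the conditions; bounded in `[1/(k-1), 1]`.
#'
#' @param data n x k numeric matrix.
#' @return scalar epsilon.
#' @export
greenhouse_geisser_epsilon <- function(data) {
  data <- as.matrix(data)
  k <- ncol(data)
  abort_if(k < 2 || nrow(data) < 3, "need n >= 3 and k >= 2")
  S <- stats::cov(data)
  abort_if(any(!is.finite(S)) || all(S == 0), "degenerate covariance")
  # epsilon from the double-centered covariance matrix
  Sc <- S - matrix(rowMeans(S), k, k) - matrix(colMeans(S), k, k,
                                               byrow = TRUE) + mean(S)
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc^2)
  abort_if(den == 0, "degenerate covariance")
  max(min(num / den, 1), 1 / (k - 1))
}

#' Friedman test with Kendall's W effect size
#'
#' Rank-based alternative to the one-way rmANOVA; ties receive average
#' ranks. Kendall's coefficient of concordance is `W = chi2 / (n (k - 1))`.
#'
#' @param data n subjects x k conditions numeric matrix.
#' @return a `stat_result` with the chi-squared statistic, df = k - 1, and
#'   Kendall's W as effect size.
#' @export
friedman_kendall <- function(data) {
  data <- as.matrix(data)
  abort_if(anyNA(data), "complete data required")
  n <- nrow(data); k <- ncol(data)
  abort_if(k < 2 || n < 2, "need n >= 2 and k >= 2")
  abort_if(all(apply(data, 1, function(r) length(unique(r)) == 1)),
           "all rows constant: ranks undefined")
  ht <- stats::friedman.test(data)
  W <- unname(ht$statistic) / (n * (k - 1))
  stat_result("friedman", unname(ht$statistic), unname(ht$parameter),
              ht$p.value, effect_size = W)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values for a jointly corrected family (when post hoc
#' comparisons span several models and frequency bands, the family contains
#' all of them at once).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(pvalues) {
  abort_if(any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1),
           "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Choose the group-comparison test from assumption screening
#'
#' Shapiro-Wilk normality per condition at `alpha`: any failure selects the
#' Friedman test. Otherwise Mauchly's sphericity screen (k > 2) selects the
#' Greenhouse-Geisser-corrected rmANOVA on failure, and the uncorrected
#' rmANOVA when both assumptions hold.
#'
#' @param data n x k numeric matrix.
#' @param alpha screening level (default 0.05).
#' @return one of `"rmANOVA"`, `"rmANOVA+GG"`, `"Friedman"`.
#' @export
assumption_screen <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  abort_if(nrow(data) < 3, "need n >= 3 subjects")
  abort_if(any(apply(data, 2, stats::sd) == 0), "constant condition column")
  shapiro_p <- apply(data, 2, function(v) stats::shapiro.test(v)$p.value)
  if (any(shapiro_p < alpha)) return("Friedman")
  if (ncol(data) > 2) {
    mfit <- stats::lm(data ~ 1)
    mp <- tryCatch(stats::mauchly.test(mfit, X = ~1)$p.value,
                   error = function(e) NA_real_)
    if (!is.na(mp) && mp < alpha) return("rmANOVA+GG")
  }
  "rmANOVA"
}

#' Run the screened group comparison
#'
#' Applies [assumption_screen()] and runs the recommended test.
#'
#' @param data n x k matrix (subjects x age groups).
#' @param alpha screening level.
#' @return a `stat_result` (the chosen test's), with the recommendation in
#'   `details$screen`.
#' @export
screened_group_test <- function(data, alpha = 0.05) {
  rec <- assumption_screen(data, alpha)
  res <- switch(rec,
                "rmANOVA" = rm_anova_oneway(data),
                "rmANOVA+GG" = rm_anova_oneway(data, force_gg = TRUE),
                "Friedman" = friedman_kendall(data))
  res$details$screen <- rec
  res
}

#' Bootstrap topography similarity to a reference (adult) map
#'
#' Each iteration resamples `group_size` participants with replacement,
#' averages their channel-wise prediction-correlation topographies and
#' Pearson-correlates the average with the reference topography.
#'
#' @param topographies participants x channels matrix.
#' @param reference numeric vector: the reference (e.g. adult group mean)
#'   topography over the same channels.
#' @param group_size resample size per iteration (default 17).
#' @param iterations bootstrap iterations (default 100).
#' @param seed integer seed (draws are seed-reproducible).
#' @return list with `mean_r` and `draws` (length `iterations`).
#' @export
bootstrap_topography_similarity <- function(topographies, reference,
                                            group_size = 17,
                                            iterations = 100, seed) {
  topographies <- as.matrix(topographies)
  abort_if(ncol(topographies) != length(reference),
           "channel sets must match")
  n <- nrow(topographies)
  draws <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      idx <- sample.int(n, group_size, replace = TRUE)
      stats::cor(colMeans(topographies[idx, , drop = FALSE]), reference)
    }, numeric(1))
  })
  list(mean_r = mean(draws), draws = draws)
}
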