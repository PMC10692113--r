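# Statistical battery: Wilcoxon, rmANOVA + Greenhouse-Geisser, Friedman +
# Kendall's W, BH-FDR, assumption screening, topography bootstrap.

test_that("wilcoxon exact path equals full sign-pattern enumeration", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$p, 0.25)

  # symmetric +/- pairs: statistic at its null centre
  expect_equal(wilcoxon_signed_rank(c(1.5, -1.5, 0.7, -0.7))$p, 1,
               tolerance = 0.15)

  set.seed(51)
  for (i in 1:6) {
    n <- sample(6:10, 1)
    x <- round(rnorm(n, sd = 3), 3)
    x <- x[x != 0]
    if (anyDuplicated(abs(x))) next
    expect_equal(wilcoxon_signed_rank(x)$p, enumerate_signed_rank_p(x),
                 tolerance = 1e-12)
  }

  # zeros dropped; paired mode is the one-sample test on differences
  expect_equal(wilcoxon_signed_rank(c(0, 1, 2, 3))$p,
               wilcoxon_signed_rank(c(1, 2, 3))$p)
  expect_equal(wilcoxon_signed_rank(c(5, 7, 9), c(4, 5, 6))$p,
               wilcoxon_signed_rank(c(1, 2, 3))$p)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0, 1, 2)), "3 nonzero")

  # large-sample path agrees with the normal approximation in wilcox.test
  set.seed(52)
  big <- rnorm(40) + 0.3
  expect_equal(wilcoxon_signed_rank(big)$p,
               suppressWarnings(stats::wilcox.test(big, exact = FALSE,
                                                   correct = TRUE))$p.value)
})

test_that("rm_anova_oneway reproduces the two-way decomposition and df bookkeeping", {
  # n = 47, k = 3 -> df (2, 92)
  set.seed(53)
  m <- matrix(rnorm(47 * 3), 47, 3)
  res_nogg <- rm_anova_oneway(m, sphericity_alpha = 0)   # never correct
  expect_equal(res_nogg$df, c(2, 92))
  res <- res_nogg

  # SS decomposition is exact
  ss <- res$details$ss
  expect_equal(ss[["total"]],
               ss[["subject"]] + ss[["condition"]] + ss[["error"]],
               tolerance = 1e-10)

  # all cells equal -> F = 0
  expect_error(rm_anova_oneway(matrix(5, 10, 3) * NA), "missing")
  res0 <- rm_anova_oneway(matrix(rep(rnorm(10), 3), 10, 3),
                          sphericity_alpha = 0)
  expect_equal(res0$statistic, 0, tolerance = 1e-20)
  expect_equal(res0$effect_size, 0, tolerance = 1e-20)

  # k = 2: F equals the squared paired t statistic
  set.seed(54)
  m2 <- matrix(rnorm(20), 10, 2)
  tstat <- stats::t.test(m2[, 1], m2[, 2], paired = TRUE)$statistic
  expect_equal(rm_anova_oneway(m2)$statistic, unname(tstat^2),
               tolerance = 1e-10)

  # cross-check F and p against aov with an Error stratum
  d <- data.frame(y = as.vector(m), subj = factor(rep(1:47, 3)),
                  cond = factor(rep(1:3, each = 47)))
  sm <- summary(stats::aov(y ~ cond + Error(subj / cond), data = d))
  f_aov <- sm[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(res_nogg$statistic, f_aov, tolerance = 1e-10)
})

test_that("greenhouse_geisser_epsilon matches a contrast-space oracle", {
  # compound symmetry -> epsilon = 1
  set.seed(55)
  base <- rnorm(40)
  cs <- sapply(1:3, function(j) base + rnorm(40, sd = 0.5))
  Sig <- diag(3) * 0.25 + 1           # population compound-symmetric
  n <- 2000
  z <- matrix(rnorm(n * 3), n) %*% chol(Sig)
  expect_equal(greenhouse_geisser_epsilon(z), 1, tolerance = 0.02)

  # oracle on arbitrary data: epsilon from an orthonormal contrast basis
  m <- matrix(rnorm(60), 20, 3) %*% matrix(c(1, 0.8, 0, 0, 1, 0.1, 0, 0, 1), 3)
  k <- 3
  C <- t(qr.Q(qr(cbind(1, diag(k))))[, 2:k])     # orthonormal contrasts
  E <- C %*% stats::cov(m) %*% t(C)
  eps_or <- sum(diag(E))^2 / ((k - 1) * sum(E^2))
  expect_equal(greenhouse_geisser_epsilon(m), eps_or, tolerance = 1e-10)

  # bounds
  expect_gte(greenhouse_geisser_epsilon(m), 1 / (k - 1))
  expect_lte(greenhouse_geisser_epsilon(m), 1)
  expect_error(greenhouse_geisser_epsilon(matrix(1, 10, 3)), "degenerate")
})

test_that("friedman_kendall reproduces the rank-sum formula and W identity", {
  # perfectly concordant rankings -> W = 1
  conc <- t(replicate(6, c(1, 5, 9))) + matrix(rnorm(18, sd = 0.01), 6)
  expect_equal(friedman_kendall(conc)$effect_size, 1, tolerance = 1e-6)

  # small table: brute-force chi-squared from within-subject ranks
  m <- matrix(c(1, 3, 2, 2, 1, 3, 3, 2, 1, 1, 2, 3), 4, 3, byrow = TRUE)
  n <- 4; k <- 3
  R <- colSums(t(apply(m, 1, rank)))
  chi_or <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  res <- friedman_kendall(m)
  expect_equal(res$statistic, chi_or, tolerance = 1e-10)
  expect_equal(res$df, k - 1)

  # identity W = chi2 / (n (k-1)) on random data
  set.seed(56)
  r <- matrix(rnorm(50), 10, 5)
  fr <- friedman_kendall(r)
  expect_equal(fr$effect_size, fr$statistic / (10 * 4), tolerance = 1e-12)

  expect_error(friedman_kendall(matrix(2, 5, 3)), "constant")
})

test_that("fdr_bh reproduces step-up adjustment and its properties", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.037), 0.037)

  set.seed(57)
  p <- runif(20)^2
  adj <- fdr_bh(p)
  expect_true(all(adj >= p))                       # never decreases
  expect_true(all(diff(adj[order(p)]) >= -1e-15)) # preserves ordering
  expect_identical(fdr_bh(p), adj)                 # deterministic
  expect_true(all(adj <= 1))
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("assumption_screen routes by normality then sphericity", {
  # multivariate normal, compound symmetric -> plain rmANOVA in the large
  # majority of runs (Shapiro at .05 on 3 levels passes ~86%, Mauchly ~95%)
  set.seed(58)
  n_runs <- 60
  recs <- replicate(n_runs, {
    base <- rnorm(25)
    assumption_screen(sapply(1:3, function(j) base + rnorm(25)))
  })
  expect_gte(mean(recs == "rmANOVA"), 0.7)

  # heavy-tailed data -> Friedman in the majority of runs
  recs2 <- replicate(n_runs, {
    assumption_screen(matrix(rnorm(75)^3, 25, 3))
  })
  expect_gt(mean(recs2 == "Friedman"), 0.5)

  expect_error(assumption_screen(matrix(rnorm(6), 2, 3)), "n >= 3")
  expect_error(assumption_screen(cbind(rnorm(10), rep(1, 10))), "constant")

  sg <- screened_group_test(matrix(rnorm(30), 10, 3))
  expect_s3_class(sg, "stat_result")
  expect_true(sg$details$screen %in% c("rmANOVA", "rmANOVA+GG", "Friedman"))
})

test_that("rm_anova p-values are uniform under the null", {
  set.seed(59)
  ps <- replicate(400, rm_anova_oneway(matrix(rnorm(36), 12, 3),
                                       sphericity_alpha = 0)$p)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("bootstrap topography similarity is seeded and order-sensitive", {
  set.seed(60)
  adult <- rnorm(30)
  same <- matrix(rep(adult, 10), 10, byrow = TRUE)
  res <- bootstrap_topography_similarity(same, adult, group_size = 5,
                                         iterations = 20, seed = 7)
  expect_true(all(abs(res$draws - 1) < 1e-12))

  res2 <- bootstrap_topography_similarity(same, adult, group_size = 5,
                                          iterations = 20, seed = 7)
  expect_identical(res, res2)                      # determinism contract

  # planted ordering: cohort A closer to the adult map than cohort B
  wins <- 0
  for (i in 1:20) {
    A <- same + matrix(rnorm(300, sd = 0.5), 10)
    B <- same + matrix(rnorm(300, sd = 2.5), 10)
    rA <- bootstrap_topography_similarity(A, adult, 5, 50, seed = i)$mean_r
    rB <- bootstrap_topography_similarity(B, adult, 5, 50, seed = i)$mean_r
    wins <- wins + (rA > rB)
  }
  expect_gte(wins, 19)

  expect_error(bootstrap_topography_similarity(same[, 1:10], adult,
                                               5, 10, seed = 1), "channel")
})
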