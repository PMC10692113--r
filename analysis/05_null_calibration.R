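#!/usr/bin/env Rscript
# Stage 5: finite-sample behaviour of the FS-S gain under the null.
#
# Cohorts are simulated with zero phonetic gain but the acoustic S/F
# confound switched on, and the one-sample Wilcoxon on cohort gains is
# run at alpha = .05. At asymptotic data volumes the gain statistic is
# centred at zero under this null; at the reduced per-participant data
# volume used here the extra phonetic regressors dilute the
# cross-validated prediction correlation, producing a systematic negative
# bias and a rejection rate far above the nominal level. This stage
# quantifies that bias so that gains from matched-size analyses are read
# against it (session CONTRASTS are unaffected, because the bias is
# common to all sessions of a participant).

library(rhymetrf)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
n_cohorts <- 20
out <- data.frame(cohort = seq_len(n_cohorts), mean_gain = NA_real_,
                  sd_gain = NA_real_, wilcoxon_p = NA_real_)
for (i in seq_len(n_cohorts)) {
  G <- gain_cohort_experiment(derive_seed(42, paste0("null", i)),
                              session_gains = 0, n_participants = 15,
                              n_trials = 3, trial_duration = 8, fs = 25,
                              n_channels = 14, n_repetitions = 1,
                              dropout_prob = 0)
  out$mean_gain[i] <- mean(G)
  out$sd_gain[i] <- sd(G)
  out$wilcoxon_p[i] <- wilcoxon_signed_rank(G[, 1])$p
}
write.csv(out, "results/tables/null_gain_calibration.csv", row.names = FALSE)

cat(sprintf("Across %d null cohorts (n = 15, 3 trials x 8 s):\n", n_cohorts))
cat(sprintf("  mean gain bias: %+.4f (cohort SD of gains ~ %.4f)\n",
            mean(out$mean_gain), mean(out$sd_gain)))
cat(sprintf("  Wilcoxon rejection rate at alpha = .05: %.2f (nominal 0.05)\n",
            mean(out$wilcoxon_p < 0.05)))
cat("The negative bias shrinks roughly as 1/(training samples); see the\n")
cat("methods vignette for the scaling analysis and its implications.\n")
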