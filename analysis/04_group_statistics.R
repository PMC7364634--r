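#!/usr/bin/env Rscript

# Longitudinal group contrasts on the simulated cohort from
# 01_simulate_cohort.R: least-squares means per group x age with
# unstructured within-animal covariance, Tukey-Kramer adjusted pairwise
# contrasts (log scale with multiplicative back-transform for power
# outcomes), terminal one-way ANOVA on atrophy, and actual/residual
# Spearman correlations of atrophy against the final dark-period outcomes.

library(tausleep)
dir.create("results", showWarnings = FALSE)

if (!file.exists("results/truth_metrics.csv")) {
  stop("run analysis/01_simulate_cohort.R first")
}
metrics <- read.csv("results/truth_metrics.csv")
atrophy <- read.csv("results/atrophy.csv")
dark <- metrics[metrics$photoperiod == "DARK", ]

log_outcomes <- c("power_delta", "power_theta", "power_total",
                  "rem_bout_count", "sleep_bout_count", "motion")
raw_outcomes <- c("pct_wake", "pct_nrem", "pct_rem")

all_ct <- list()
for (oc in c(log_outcomes, raw_outcomes)) {
  fit <- fit_repeated_measures(dark, oc, log_scale = oc %in% log_outcomes)
  ct <- pairwise_contrasts(fit)
  ct$outcome <- oc
  if (!"ratio" %in% names(ct)) ct$ratio <- ct$ratio_lo <- ct$ratio_hi <- NA
  all_ct[[oc]] <- as.data.frame(ct)
}
contrasts <- do.call(rbind, all_ct)
write.csv(contrasts, "results/contrasts.csv", row.names = FALSE)

tg_wt <- contrasts[(contrasts$group1 == "Tg" & contrasts$group2 == "WT") |
                     (contrasts$group1 == "WT" & contrasts$group2 == "Tg"), ]
cat("Tg vs WT, ages with adjusted p < 0.05 (dark period):\n")
for (oc in unique(tg_wt$outcome)) {
  sig <- tg_wt$age_week[tg_wt$outcome == oc & tg_wt$significant]
  cat(sprintf("  %-16s %s\n", oc,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
}

av <- one_way_anova(atrophy$thickness_mm, atrophy$group)
cat(sprintf("\nTerminal thickness ANOVA: F(%d, %d) = %.1f, p = %.2g\n",
            av$df_between, av$df_within, av$F, av$p))
write.csv(av$posthoc, "results/atrophy_posthoc.csv", row.names = FALSE)

fin <- dark[dark$age_week == max(dark$age_week) &
              dark$outcome == "pct_nrem", ]
fin <- fin[match(atrophy$animal_id, fin$animal_id), ]
for (mode in c("actual", "residual")) {
  r <- correlate_with_atrophy(fin$value, atrophy$thickness_mm,
                              atrophy$group, mode = mode)
  cat(sprintf("Final dark NREM%% vs thickness, %s: rs = %.2f, p = %.2g\n",
              mode, r$rs, r$p))
}
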