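#!/usr/bin/env Rscript
# Step 1 — the task design and its derived quantities.
#
# Builds the canonical 100-trial design table, checks its structural
# properties, and exports the design and the 12 strategy response
# profiles for the later steps.

suppressPackageStartupMessages(library(wptstrategy))
dir.create("results", showWarnings = FALSE)

design <- wpt_design(n_repeats = 1L)

cat("== Task design ==\n")
cat(sprintf("patterns: %d | trials: %d (A %d / B %d) | scored: %d (A %d / B %d)\n",
            nrow(design), sum(design$n_total), sum(design$n_outcome_A),
            sum(design$n_outcome_B), scored_trial_count(design),
            scored_trial_count(design, "A"), scored_trial_count(design, "B")))
cat("marginal cue-outcome probabilities:",
    sprintf("cue%d=%.2f", 1:4, vapply(1:4, cue_outcome_probability,
                                      numeric(1), design = design)), "\n")
cat(sprintf("individual above-chance threshold: %d of %d correct (chi2 = %.3f)\n",
            above_chance_threshold(scored_trial_count(design)),
            scored_trial_count(design),
            chance_chisq_stat(above_chance_threshold(scored_trial_count(design)),
                              scored_trial_count(design))))

cat("\nexpected accuracy of each strategy over the scored trials:\n")
acc <- vapply(strategy_names(), function(s)
  expected_accuracy(strategy_profile(s, design), design), numeric(1))
print(round(sort(acc, decreasing = TRUE), 4))

write_design_csv(design, "results/design.csv")
write_matrix_csv(strategy_profiles(design), "results/strategy_profiles.csv")
cat("\nwrote results/design.csv and results/strategy_profiles.csv\n")
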