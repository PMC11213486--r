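#!/usr/bin/env Rscript
# Step 5 -- transitions of the condition-specific state after switching.
#
# For each trial with a scored predecessor: the transition magnitude
# (initial Cp minus where the state stood with respect to the new task just
# before the cue), the time to reach Cp >= 0.6, the suppression-load
# regression (previous final Cp predicting the post-switch initial Cp and
# the time to criterion), and the mixed logistic regression of trial
# success on trial-mean Cp.

suppressPackageStartupMessages(library(huntswitch))

cp <- list(windows = read.csv("results/cp_windows.csv"),
           trials = read.csv("results/cp_trials.csv"))
rec <- transition_records(cp)
write.csv(rec, "results/transition_records.csv", row.names = FALSE)

sw <- rec$transition[rec$is_switch]
tt <- t.test(sw, alternative = "greater")
cat(sprintf("Mean transition after switch: %.2f (n = %d, p = %.2g)\n",
            mean(sw), length(sw), tt$p.value))

dump_fit <- function(fit, path, label) {
  write.csv(fit$coefficients, path, row.names = FALSE)
  cat("\n", label, if (fit$flagged) " [fixed-effects fallback]", ":\n",
      sep = "")
  print(fit$coefficients, digits = 3)
}

dump_fit(suppression_load_model(rec), "results/suppression_load.csv",
         "Suppression load -> initial Cp")
dump_fit(suppression_load_model(rec, outcome = "time_to_criterion"),
         "results/suppression_ttc.csv",
         "Suppression load -> time to criterion")

meta <- cohort_meta(readRDS("results/cohort.rds"))
trials <- merge(cp$trials,
                meta[, c("subject_id", "trial_index", "outcome")])
trials$success <- trials$outcome == "success"
dump_fit(success_cp_model(trials), "results/success_cp.csv",
         "Trial success ~ mean Cp (logistic)")

cat("\nWrote transition_records.csv and regression tables under results/\n")
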