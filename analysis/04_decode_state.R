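#!/usr/bin/env Rscript
# Step 4 -- decode the task condition from the fitted parameters and build
# the condition-specific state (Cp).
#
# Model parameters are averaged within trial (one (theta, tau, mu) triple
# per trial) and a linear SVM with Platt-calibrated posteriors is trained
# per subject under leave-one-trial-out cross-validation. Cp is the
# task-appropriate posterior per 500-ms window; a within-subject label
# permutation gives the chance-level reference.

suppressPackageStartupMessages(library(huntswitch))

fits <- read.csv("results/window_fits.csv")
features <- trial_features(fits)
write.csv(features, "results/trial_features.csv", row.names = FALSE)

decoder <- fit_decoder_loto(features)
cat(sprintf("LOTO decoding accuracy: %.1f%% (subjects: %s)\n",
            100 * decoder$accuracy,
            paste(sprintf("%.0f%%", 100 * decoder$subject_accuracy),
                  collapse = ", ")))

set.seed(44)
nul <- decoding_null(features, n_perm = 100L, observed = decoder$accuracy)
cat(sprintf("Permutation null: mean %.1f%%, empirical p = %.4f\n",
            100 * nul$mean, nul$p_value))

cp <- cp_timecourse(fits, features)
write.csv(cp$windows, "results/cp_windows.csv", row.names = FALSE)
write.csv(cp$trials, "results/cp_trials.csv", row.names = FALSE)
cat(sprintf("Cp: group mean initial %.2f, trial mean %.2f, median trial %.2f\n",
            mean(cp$trials$initial_cp), mean(cp$trials$mean_cp),
            median(cp$trials$mean_cp)))
cat("\nWrote trial_features.csv, cp_windows.csv, cp_trials.csv\n")
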