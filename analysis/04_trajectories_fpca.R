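#!/usr/bin/env Rscript
# Stage 4: pupil trajectories and functional PCA.
#
# Regenerates the pupil sample streams from the stored config (deterministic
# under the saved seed; the raw stream is too large to keep on disk), builds
# baseline-corrected, time-normalized, spline-smoothed trajectories, fits
# FPCA, applies the >85% cumulative / >5% individual retention rule, and
# tests score-condition associations.

library(loomdyn)

cfg <- read_sim_config("results/config.json")
trials <- read_trials_csv("results/trials_screened.csv")
trials <- trials[trials$included, ]

pupil <- generate_pupil(trials, cfg)
cat(sprintf("generated %d pupil samples for %d trials\n",
            nrow(pupil), nrow(trials)))

traj <- build_trajectories(pupil, trials)
cat(sprintf("built %d trajectories; excluded %d (%s)\n",
            nrow(traj$X), nrow(traj$excluded),
            paste(names(table(traj$excluded$reason)),
                  table(traj$excluded$reason), collapse = ", ")))
utils::write.csv(data.frame(traj$index, traj$X), "results/trajectories.csv",
                 row.names = FALSE)

fp <- fit_fpca(traj$X, traj$grid)
ret <- retain_components(fp)
write_fpca_json(fp, "results/fpca.json")
cat(sprintf("FPCA shares: %s; retained components: %s (cumulative %.1f%%)\n",
            paste(sprintf("%.1f%%", 100 * fp$explained_share[1:4]),
                  collapse = " "),
            paste(ret$retained, collapse = ","),
            100 * sum(fp$explained_share[ret$retained])))

key <- paste(trials$subject_id, trials$trial)
tkey <- paste(traj$index$subject_id, traj$index$trial)
m <- match(tkey, key)
scores <- data.frame(traj$index, fp$scores[, ret$retained, drop = FALSE])
write_trials_csv(scores, "results/fpca_scores.csv")

tests <- score_condition_tests(
  fp$scores[, ret$retained, drop = FALSE],
  data.frame(arm = factor(trials$arm[m]),
             is_threat = factor(trials$is_threat[m]),
             jttc = trials$jttc[m]))
write_trials_csv(tests, "results/fpca_score_tests.csv")
sig <- tests[tests$p_adj < 0.05, c("component", "variable", "type", "p_adj")]
cat("score-condition associations at BH 5%:\n")
print(sig, row.names = FALSE)
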