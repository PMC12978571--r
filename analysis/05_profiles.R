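#!/usr/bin/env Rscript
# Stage 5: two-level behavioral-pupillary profiling.
#
# Clusters trials on log jTTC (early vs late responders), then on the
# retained FPCA scores within each behavioral subgroup (k chosen by
# Calinski-Harabasz + silhouette rank-sum), checks bootstrap stability and
# cross-validated assignment accuracy, and correlates per-subject subgroup
# proportions with the fitted power-law parameters.

library(loomdyn)

trials <- read_trials_csv("results/trials_screened.csv")
trials <- trials[trials$included, ]
scores <- read_trials_csv("results/fpca_scores.csv")
fits <- read_trials_csv("results/power_law_fits.csv")

key <- paste(trials$subject_id, trials$trial)
m <- match(paste(scores$subject_id, scores$trial), key)
jt <- trials$jttc[m]
S <- as.matrix(scores[, grep("^X", names(scores)), drop = FALSE])

pr <- assign_profiles(jt, S, seed = 11)
write_trials_csv(data.frame(scores[, c("subject_id", "trial")],
                            profile = pr$profile),
                 "results/profiles.csv")
cat(sprintf("level 1: E centroid %.2f s, L centroid %.2f s (silhouette %.2f)\n",
            exp(pr$level1$centroids_log["E"]),
            exp(pr$level1$centroids_log["L"]), pr$level1$silhouette))

stability <- list()
for (g in c("E", "L")) {
  l2 <- pr$level2[[g]]
  if (isTRUE(l2$unclustered)) next
  i <- pr$labels1 == g
  Z <- scale(S[i, , drop = FALSE])
  bs <- bootstrap_stability(Z, l2$labels, l2$k, n_boot = 1000, seed = 12)
  cv <- cross_validate_clusters(Z, l2$labels, l2$k, seed = 12)
  stability[[g]] <- list(k = l2$k, bootstrap_mean = bs$mean,
                         bootstrap_sd = bs$sd, cv_mean = cv$mean,
                         cv_sd = cv$sd, weak = l2$weak)
  cat(sprintf("level 2 (%s): k = %d; bootstrap ARI %.3f +/- %.3f; CV accuracy %.3f +/- %.3f\n",
              g, l2$k, bs$mean, bs$sd, cv$mean, cv$sd))
}
jsonlite::write_json(stability, "results/stability.json",
                     digits = NA, auto_unbox = TRUE, pretty = TRUE)

sign_tab <- profile_sign_summary(pr$profile, S)
write_trials_csv(sign_tab, "results/profile_signs.csv")
cat("profile PC-score sign summary:\n")
print(sign_tab, row.names = FALSE)

pc <- proportion_correlations(scores$subject_id, pr$labels1, fits)
write_trials_csv(pc, "results/proportion_correlations.csv")
cat("subject-level E/L proportion vs power-law parameters:\n")
print(pc, row.names = FALSE)
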