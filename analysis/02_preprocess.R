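#!/usr/bin/env Rscript
# Stage 2: behavioral screening.
#
# Applies the per-subject +/-5 SD jTTC outlier rule (after any technical
# artifacts) and writes the screened trial table plus an exclusion log.

library(loomdyn)

trials <- read_trials_csv("results/trials_raw.csv")
v <- validate_inputs(trials)
stopifnot(v$ok)

trials <- filter_jttc_outliers(trials)
write_trials_csv(trials, "results/trials_screened.csv")

excl <- trials[!trials$included,
               c("subject_id", "trial", "jttc", "exclusion_reason")]
jsonlite::write_json(excl, "results/behavior_exclusions.json",
                     digits = NA, pretty = TRUE)

cat(sprintf("screened %d trials: %d excluded (%.2f%%)\n",
            nrow(trials), sum(!trials$included),
            100 * mean(!trials$included)))
cat(sprintf("short trials (< 2300 ms, excluded later from phase analyses): %d (%.1f%%)\n",
            sum(trials$keypress_ms < 2300),
            100 * mean(trials$keypress_ms < 2300)))
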