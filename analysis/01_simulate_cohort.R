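#!/usr/bin/env Rscript
# Stage 1: simulate the reference cohort (8 robust, 13 pre-frail, 6 frail
# participants, each performing the tea-making and gardening task once)
# at the shipped calibration and write the raw recordings plus manifest.
#
# Output: results/recordings/*.csv, results/recordings/manifest.csv

library(adlkin)

seed <- 1L
cfg <- default_sim_config(seed = seed)
cohort <- simulate_cohort(cfg, c(R = 8, P = 13, F = 6))
manifest <- write_cohort(cohort, "results/recordings")

groups <- vapply(cohort, `[[`, character(1), "group")
cat(sprintf("Simulated %d participants (R=%d, P=%d, F=%d), %d recordings.\n",
            length(cohort), sum(groups == "R"), sum(groups == "P"),
            sum(groups == "F"), nrow(manifest)))
cat(sprintf("Frailty scores: %s\n",
            paste(sort(vapply(cohort, `[[`, numeric(1), "score")),
                  collapse = " ")))
dur <- vapply(cohort, function(p) {
  vapply(p$recordings, function(r) length(r$t) / r$sample_rate, numeric(1))
}, numeric(2))
cat(sprintf("Trial durations: TEA %.0f-%.0f s, GARDEN %.0f-%.0f s.\n",
            min(dur["TEA", ]), max(dur["TEA", ]),
            min(dur["GARDEN", ]), max(dur["GARDEN", ])))
cat("Recordings written to results/recordings/.\n")
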