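#!/usr/bin/env Rscript
# Stage 2: recording quality control.
#
# A recording is kept only if its tracking ratio is strictly above 75% and
# its total fixation time strictly above 50% of the stimulus duration.
# The simulated fixation exports carry no raw 120 Hz samples, so the ratio
# test is skipped (as it would be for any fixation-only export without a
# vendor metadata column) and the fixation-time gate does the work.

library(gazehmm)

cfg <- default_config()
sps <- read_fixation_table("results/data/fixations.csv", cfg)
qc <- qc_scanpaths(sps, stimulus_duration_ms = 120000, cfg)

dir.create("results", showWarnings = FALSE)
write.csv(qc, "results/qc_report.csv", row.names = FALSE)
cat(sprintf("QC: %d of %d recordings pass (fixation-time fractions %.2f-%.2f)\n",
            sum(qc$passed), nrow(qc),
            min(qc$fixation_time_fraction), max(qc$fixation_time_fraction)))
if (any(!qc$passed)) print(qc[!qc$passed, ])
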