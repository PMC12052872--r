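#!/usr/bin/env Rscript
# Simulate the study dataset: 8 participants, 3 SAT regimes x 2 lexicality
# conditions, 20 trials per cell, two-channel 1000-Hz EMG with ground
# truth. Writes the raw-data layout consumed by the rest of the workflow.

library(emgchrono)

out <- "results/data"
spec <- generator_spec(n_participants = 8, trials_per_cell = 20)
ds <- generate_dataset(spec, seed = 42, dir = out)

cat("participants:", length(ds$recordings), "\n")
cat("event rows:  ", nrow(ds$events), "\n")
cat("recording minutes per participant:",
    round(nrow(ds$recordings[[1]]$signal) / spec$sampling_rate / 60, 1),
    "\n")
cat("ground truth: partial errors programmed on",
    sum(ds$truth$partial_kind == "partial_error", na.rm = TRUE),
    "trials; no-response trials:", sum(ds$truth$no_response), "\n")
cat("written to", out, "\n")
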