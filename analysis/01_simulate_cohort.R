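#!/usr/bin/env Rscript
# Simulate the study cohort: 41 TD participants and 124 ASD participants
# (35 latently over-responsive, 89 under-responsive) watching three amusing
# clips at 24 frames/s, with frame-level AU6/AU12 evidence traces, metadata
# and caregiver scales. Writes results/traces.csv, results/participants.csv
# and the generating configuration.
#
# Usage: Rscript analysis/01_simulate_cohort.R [seed]

suppressMessages(library(aumix))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)

write_cohort_config(cfg, "results/cohort_config.json")
write_traces(cohort$traces, "results/traces.csv")
write_participants(cohort$participants, "results/participants.csv")

errs <- validate_inputs(cohort$traces, cohort$participants)
stopifnot(nrow(errs) == 0)

n <- table(cohort$participants$group)
cat(sprintf("simulated %d participants (TD %d, ASD %d), %d trace rows\n",
            nrow(cohort$participants), n[["TD"]], n[["ASD"]],
            nrow(cohort$traces)))
cat("latent ASD split:",
    sum(cohort$participants$true_subgroup == "over"), "over /",
    sum(cohort$participants$true_subgroup == "under"), "under\n")
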