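#!/usr/bin/env Rscript
# Rank-based covariate-adjusted group contrasts (ASD vs TD, each subgroup vs
# TD, over vs under) and partial Spearman correlations between the four AU
# features and the caregiver scales, overall and within each subgroup.
# Writes results/report.json and the report tables under results/tables/.
#
# Usage: Rscript analysis/04_group_statistics.R

suppressMessages(library(aumix))
features <- read_features("results/features.csv")
participants <- read_participants("results/participants.csv")
sub <- tryCatch(read.csv("results/subgroups.csv"), error = function(e) NULL)
subgroup <- if (!is.null(sub)) setNames(sub$subgroup, sub$participant_id)

report <- build_report(features, participants, subgroup)
jsonlite::write_json(unclass(report), "results/report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     dataframe = "columns", na = "null")
write_report_tables(report, "results/tables")

cat(render_report(report), sep = "\n")
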