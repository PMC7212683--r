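#!/usr/bin/env Rscript
# Reduce the frame-level evidence traces to the four per-participant
# features: average AU12, average AU6 (mean evidence over detected frames,
# averaged across the three videos) and AUC AU12, AUC AU6 (area under the
# absolute evidence curve, evidence-seconds). Writes results/features.csv.
#
# Usage: Rscript analysis/02_extract_features.R

suppressMessages(library(aumix))
traces <- read_traces("results/traces.csv")
participants <- read_participants("results/participants.csv")

features <- extract_features(traces)
write_features(features, "results/features.csv")

m <- merge(features, participants, by = "participant_id")
cat(sprintf("extracted features for %d participants\n", nrow(features)))
for (g in c("TD", "ASD")) {
  s <- m[m$group == g, ]
  cat(sprintf("%-3s avg AU12 %.2f (%.2f)  avg AU6 %.2f (%.2f)  AUC AU12 %.1f  AUC AU6 %.1f\n",
              g, mean(s$avg_au12), sd(s$avg_au12), mean(s$avg_au6),
              sd(s$avg_au6), mean(s$auc_au12), mean(s$auc_au6)))
}
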