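#!/usr/bin/env Rscript
# Stage 3: fingerprint grouping.
#
# Single-linkage grouping of the sized fingerprints under the default
# matching policy (major +/-1 bp, minors +/-2 bp, interval-preserving
# matching up to a 4 bp common shift for linked dual-peak organisms).
# Reads results/profiles.tsv, writes results/groups.tsv and
# results/membership.tsv.

suppressPackageStartupMessages(library(isrtyper))

profiles <- read_profiles("results/profiles.tsv")
g <- group_profiles(profiles, match_policy())
write_grouping(g, "results/groups.tsv", "results/membership.tsv")

sizes <- g$groups$n[!g$groups$is_unique]
cat(sprintf("%d groups over %d isolates; %d multi-isolate groups (sizes %d-%d), %d unique profiles, %d failed\n",
            nrow(g$groups), nrow(g$membership), length(sizes),
            if (length(sizes)) min(sizes) else 0L,
            if (length(sizes)) max(sizes) else 0L,
            sum(g$groups$is_unique), length(g$failed_ids)))
big <- g$groups[order(-g$groups$n), ][1:5, ]
cat("largest groups (consensus major/minors):\n")
for (i in seq_len(nrow(big))) {
  cat(sprintf("  %s  n=%-3d  %d/[%s]\n", big$group_id[i], big$n[i],
              big$consensus_major[i], big$consensus_minors[i]))
}
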