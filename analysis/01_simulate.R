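#!/usr/bin/env Rscript
# Stage 1: simulate the isolate collection.
#
# Census of the packaged phylotype panel (742 isolates over 43 phylotypes,
# pilot + main study arms), plus the bookkeeping extras the study design
# implies: 4 failed electropherograms, 22 isolates in fingerprint groups
# that never get sequenced, and 3 strain mixtures ("enrichments").
# Writes results/isolates.tsv and a seed-bearing run manifest.

suppressPackageStartupMessages(library(isrtyper))
seed <- 1
dir.create("results", showWarnings = FALSE)

panel <- load_phylotype_panel()
cat(sprintf("panel: %d phylotypes, %d isolates (%d pilot, %d main)\n",
            nrow(panel), sum(panel$n_pilot + panel$n_main),
            sum(panel$n_pilot), sum(panel$n_main)))

rec <- sample_isolates(panel, "census", wobble_scale = 1, seed = seed)
rec <- inject_artifacts(rec, n_failures = 0, n_mixtures = 3, seed = seed)
extra <- sample_isolates(panel, "resample", n = 4, wobble_scale = 1,
                         seed = seed + 1)
extra$trace_failed <- TRUE
extra$isolate_id <- sprintf("iso%04d", nrow(rec) + seq_len(nrow(extra)))
rec <- rbind(rec, extra)
rec <- append_unassigned_isolates(rec, n = 22, seed = seed)

write_isolates(rec, "results/isolates.tsv")
jsonlite::write_json(
  list(stage = "simulate", seed = seed, n_isolates = nrow(rec),
       n_failed = sum(rec$trace_failed), n_mixtures = sum(rec$is_mixture),
       n_never_sequenced = sum(rec$sequencing_excluded)),
  "results/simulate_manifest.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("wrote %d isolate records (%d trace-failed, %d mixtures, %d never-sequenced)\n",
            nrow(rec), sum(rec$trace_failed), sum(rec$is_mixture),
            sum(rec$sequencing_excluded)))
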