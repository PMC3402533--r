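#!/usr/bin/env Rscript
# Stage 5: phenotype scoring and summary tables.
#
# Tabulates the 4-point acid and H2O2 scores, joint categories and the
# double-strong probiotic-candidate subset per study arm; builds the
# per-phylotype summary (counts, modal fingerprints, modal scores,
# double-strong counts); counts detected taxa under the 97% novelty
# threshold. Reads results/isolates.tsv, profiles.tsv,
# identifications.tsv; writes results/phenotypes_{pilot,main}.tsv,
# results/by_phylotype.tsv, results/taxa_counts.json.

suppressPackageStartupMessages(library(isrtyper))

rec <- read_isolates("results/isolates.tsv")
profiles <- read_profiles("results/profiles.tsv")
ids <- utils::read.delim("results/identifications.tsv",
                         stringsAsFactors = FALSE)

for (arm in c("pilot", "main")) {
  tab <- tabulate_phenotypes(rec, arm)
  utils::write.table(tab, sprintf("results/phenotypes_%s.tsv", arm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  joint <- tab[tab$block == "joint", ]
  cat(sprintf("%s arm (N = %d): double-positive %d%%, double-strong %d%%\n",
              arm, sum(tab$n[tab$block == "acid"]),
              joint$pct[joint$level == "double_positive"],
              joint$pct[joint$level == "double_strong"]))
}

by_phy <- summarize_by_phylotype(rec, ids, profiles)
utils::write.table(by_phy, "results/by_phylotype.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("per-phylotype summary: %d labels, %d double-strong isolates in total\n",
            nrow(by_phy), sum(by_phy$double_strong_n)))

taxa <- count_taxa(load_phylotype_panel())
jsonlite::write_json(taxa, "results/taxa_counts.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("taxa: %d named species in %d genera, plus %d novel groups (<97%% identity)\n",
            taxa$n_named_species, taxa$n_genera, taxa$n_novel_groups))
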