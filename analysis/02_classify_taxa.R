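#!/usr/bin/env Rscript
# Filter, rarefy and classify taxa into regionally abundant / rare /
# intermediate fractions; summarize occupancy.

suppressMessages(library(fungalassembly))

tab <- read_community_table("results/data/community.tsv")
tab <- filter_low_count_taxa(tab, min_reads = 8)
tab <- rarefy_table(tab, depth = min(9080, min(sample_depths(tab))), seed = 1)
write_community_table(tab, "results/data/community_rarefied.tsv")

cls <- classify_taxa(tab)
write.table(cls, "results/classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tot <- colSums(tab$counts)
for (lab in c("abundant", "rare")) {
  ids <- cls$taxon_id[cls$regional_label == lab]
  cat(sprintf("%s: %d ASVs (%.1f%% of taxa) holding %.2f%% of reads\n",
              lab, length(ids), 100 * length(ids) / nrow(cls),
              100 * sum(tot[ids]) / sum(tot)))
}
occ_ab <- cls$occupancy[cls$regional_label == "abundant"]
cat(sprintf("%.1f%% of abundant ASVs occur in more than half the samples\n",
            100 * mean(occ_ab > 0.5)))
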