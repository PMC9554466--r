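#!/usr/bin/env Rscript
# Distance-decay of community similarity, PERMANOVA across vegetation
# types, and an NMDS ordination table per subcommunity.

suppressMessages(library(fungalassembly))

tab <- read_community_table("results/data/community_rarefied.tsv")
cls <- read.delim("results/classification.tsv")
meta <- read_sample_metadata("results/data/metadata.csv")
geo <- geographic_distance(meta)

for (lab in c("abundant", "rare")) {
  st <- subset_community(tab, taxa = cls$taxon_id[cls$regional_label == lab])
  keep <- rowSums(st$counts) > 0
  st <- subset_community(st, samples = rownames(st$counts)[keep])
  bc <- bray_curtis(st)
  g <- geo[rownames(bc), rownames(bc)]
  fit <- ddr_fit(bc, g, permutations = 999, seed = 7)
  jsonlite::write_json(unclass(fit), sprintf("results/ddr_%s.json", lab),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s DDR: slope %.3g per km (%.3g per 1000 km), r2 %.3f, p_perm %.3g\n",
              lab, fit$slope, fit$slope_per_1000km, fit$r2, fit$p_perm))

  veg <- meta$vegetation_type[match(rownames(bc), meta$sample_id)]
  pmv <- permanova(bc, veg, permutations = 999, seed = 7)
  cat(sprintf("%s PERMANOVA across vegetation types: F %.2f, R2 %.3f, p %.3g\n",
              lab, pmv$pseudo_F, pmv$R2, pmv$p))

  nm <- nmds_coords(bc, k = 2, seed = 7)
  write.csv(data.frame(sample_id = rownames(nm$points), nm$points,
                       vegetation_type = veg),
            sprintf("results/nmds_%s.csv", lab), row.names = FALSE)
}
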