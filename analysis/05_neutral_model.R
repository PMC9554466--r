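#!/usr/bin/env Rscript
# Sloan neutral community model per subcommunity: migration rate m and
# goodness of fit R2 from the occurrence-frequency vs abundance relation.

suppressMessages(library(fungalassembly))

tab <- read_community_table("results/data/community_rarefied.tsv")
cls <- read.delim("results/classification.tsv")
N <- unique(sample_depths(tab))[1]

fits <- list()
for (lab in c("abundant", "rare")) {
  st <- subset_community(tab, taxa = cls$taxon_id[cls$regional_label == lab])
  fit <- tryCatch(suppressWarnings(fit_ncm(st, N = N)), error = function(e) e)
  if (inherits(fit, "error")) {
    cat(lab, "subcommunity: fit not possible:", conditionMessage(fit), "\n")
    next
  }
  fits[[lab]] <- fit
  write.csv(fit$taxa, sprintf("results/ncm_taxa_%s.csv", lab), row.names = FALSE)
  jsonlite::write_json(list(m = fit$m, r2 = fit$r2, N = fit$N, d = fit$d,
                            n_taxa = fit$n_taxa),
                       sprintf("results/ncm_%s.json", lab),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: m = %.3f, R2 = %.3f (%d taxa)\n", lab, fit$m, fit$r2,
              fit$n_taxa))
}
if (length(fits) == 2 && fits$abundant$r2 > fits$rare$r2)
  cat("neutral processes fit the abundant subcommunity better than the rare\n")
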