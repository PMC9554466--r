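#!/usr/bin/env Rscript
# What drives the beta-deviations? Collinearity-pruned covariates enter
# forward-selected MRM; variance is partitioned into pure spatial, pure
# environmental and shared fractions; hierarchical partitioning ranks
# the plant / soil / climate / space groups; a recursive path model
# separates direct from indirect effects.

suppressMessages(library(fungalassembly))

tab <- read_community_table("results/data/community_rarefied.tsv")
cls <- read.delim("results/classification.tsv")
meta <- read_sample_metadata("results/data/metadata.csv")
geo <- geographic_distance(meta)

groups <- list(soil = c("SM", "pH", "TSN", "SAN", "TSP", "TOC"),
               climate = c("MAT", "aridity"),
               plant = c("PLC", "SLA", "LCN", "LNP", "PHight", "Cwidth", "richness"))
covs <- meta[, unlist(groups)]
rownames(covs) <- meta$sample_id
pruned <- collinearity_prune(covs, threshold = 0.6)
cat("collinearity pruning dropped:", paste(pruned$dropped, collapse = ", "), "\n")
env_mats <- lapply(pruned$retained, function(v) env_distance(covs[, v, drop = FALSE]))
names(env_mats) <- pruned$retained

for (lab in c("abundant", "rare")) {
  bd <- read.csv(sprintf("results/beta_deviation_%s.csv", lab))
  class(bd) <- c("beta_deviation", "data.frame")
  dev_m <- deviation_matrix(bd)
  while (anyNA(dev_m)) {
    worst <- which.max(rowSums(is.na(dev_m)))
    dev_m <- dev_m[-worst, -worst, drop = FALSE]
  }
  lbl <- rownames(dev_m)
  space_set <- list(geo = geo[lbl, lbl])
  env_set <- lapply(env_mats, function(m) m[lbl, lbl])

  fs <- forward_select(dev_m, env_set, alpha = 0.05, permutations = 999,
                       seed = 31)
  cat(sprintf("%s: forward selection kept {%s}\n", lab,
              paste(fs$selected, collapse = ", ")))
  if (length(fs$selected)) {
    vpa <- vpa_two_sets(dev_m, space_set, env_set[fs$selected])
  } else {
    lt <- lower.tri(dev_m)
    r2 <- summary(lm(dev_m[lt] ~ space_set$geo[lt]))$r.squared
    vpa <- list(pure_space = r2, pure_env = 0, shared = 0,
                unexplained = 1 - r2, r2_full = r2)
  }
  cat(sprintf("%s VPA: pure space %.2f%%, pure env %.2f%%, shared %.2f%%, unexplained %.2f%%\n",
              lab, 100 * vpa$pure_space, 100 * vpa$pure_env,
              100 * vpa$shared, 100 * vpa$unexplained))
  jsonlite::write_json(vpa[c("pure_space", "pure_env", "shared",
                             "unexplained", "r2_full")],
                       sprintf("results/vpa_%s.json", lab),
                       auto_unbox = TRUE, digits = NA)

  hp_groups <- lapply(groups, function(vars) env_set[intersect(vars, names(env_set))])
  hp_groups <- hp_groups[vapply(hp_groups, length, integer(1)) > 0]
  hp_groups$space <- space_set
  hp <- hierarchical_partition(dev_m, hp_groups)
  cat(sprintf("%s hierarchical partitioning: %s\n", lab,
              paste(sprintf("%s %.2f%%", names(hp$contributions),
                            100 * hp$contributions), collapse = ", ")))

  grp_dist <- function(vars) {
    vars <- intersect(vars, pruned$retained)
    if (!length(vars)) return(NULL)
    env_distance(covs[lbl, vars, drop = FALSE])
  }
  vars <- list(space = geo[lbl, lbl], soil = grp_dist(groups$soil),
               climate = grp_dist(groups$climate),
               plant = grp_dist(groups$plant), fungal_deviation = dev_m)
  vars <- vars[!vapply(vars, is.null, logical(1))]
  mediators <- setdiff(names(vars), c("space", "fungal_deviation"))
  spec <- path_spec(rbind(data.frame(from = "space", to = mediators),
                          data.frame(from = c(mediators, "space"),
                                     to = "fungal_deviation")))
  pd <- lapply(vars, function(m) m[lower.tri(m)])
  pfit <- fit_path_model(spec, as.data.frame(pd))
  cat(sprintf("%s path model: outcome R2 = %.2f%%\n", lab,
              100 * pfit$r2_outcome))
  writeLines(path_to_dot(spec, pfit),
             sprintf("results/path_%s.dot", lab))
  jsonlite::write_json(list(r2_outcome = pfit$r2_outcome,
                            effects = pfit$effects),
                       sprintf("results/path_%s.json", lab),
                       auto_unbox = TRUE, digits = NA)
}
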