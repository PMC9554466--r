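#' Default pipeline configuration
#'
#' @param out_dir output directory for run artifacts
#' @param seed master seed; per-stage seeds are derived from it so stages
#'   can be rerun independently
#' @param min_reads taxon total-read filter threshold (default 8)
#' @param depth rarefaction depth (default 9080)
#' @param reps null-model replicates (default 999)
#' @param permutations permutations for MRM/Mantel-type tests (default 999)
#' @param alpha forward-selection entry threshold (default 0.05)
#' @param subcommunities which regional subsets to analyse
#' @param generator arguments forwarded to [sim_config()] (used when no
#'   input table is given)
#' @param table_path,metadata_path optional input files; when `NULL` the
#'   synthetic generator supplies the data
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 1, min_reads = 8, depth = 9080,
                            reps = 999, permutations = 999, alpha = 0.05,
                            subcommunities = c("abundant", "rare"),
                            generator = list(), table_path = NULL,
                            metadata_path = NULL) {
  cfg <- list(out_dir = out_dir, seed = seed, min_reads = min_reads,
              depth = depth, reps = reps, permutations = permutations,
              alpha = alpha, subcommunities = subcommunities,
              generator = generator, table_path = table_path,
              metadata_path = metadata_path)
  stopifnot(is.character(out_dir), reps >= 99, permutations >= 1,
            alpha > 0, alpha <= 1,
            all(subcommunities %in% c("abundant", "rare")))
  class(cfg) <- "pipeline_config"
  cfg
}

# deterministic per-stage seed derived from the master seed
stage_seed <- function(master, stage) {
  (as.integer(master) * 7919L +
     sum(utf8ToInt(stage)) * 104729L) %% 2147483647L
}

# covariate grouping used for hierarchical partitioning and path analysis
covariate_groups <- function() {
  list(soil = c("SM", "pH", "TSN", "SAN", "TSP", "TOC"),
       climate = c("MAT", "aridity"),
       plant = c("PLC", "SLA", "LCN", "LNP", "PHight", "Cwidth", "richness"))
}

#' Load a pipeline configuration from YAML
#'
#' The YAML document holds [pipeline_config()] fields by name; a
#' `generator` block is forwarded to [sim_config()]. Fields given in
#' `...` override the file.
#'
#' @param path YAML file path
#' @param ... overrides for individual fields
#' @return a [pipeline_config()]
#' @export
load_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(pipeline_config, cfg)
}

#' Run the full assembly-inference pipeline
#'
#' Stages, in fixed order: data intake (synthetic generator by default),
#' low-count filter, rarefaction, abundant/rare classification, and per
#' subcommunity: niche breadth (B, Bcom), Bray-Curtis beta-diversity,
#' null-model beta-deviations, Sloan neutral-model fit, distance-decay
#' regression, PERMANOVA across vegetation types, forward-selected MRM
#' with two-set variation partitioning and hierarchical partitioning of
#' the beta-deviations, and recursive path analysis. All artifacts are
#' written under `config$out_dir` together with a `manifest.json`
#' recording the configuration and derived per-stage seeds; reruns with
#' the same configuration and seed are numerically identical.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the main in-memory results
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  seeds <- vapply(c("simulate", "rarefy", "nulldev", "ncm", "ddr", "mrm", "perm"),
                  function(s) stage_seed(config$seed, s), numeric(1))

  ## intake
  if (is.null(config$table_path)) {
    gen <- do.call(sim_config, c(config$generator,
                                 list(seed = as.integer(seeds[["simulate"]]) %% 1000000L)))
    sim <- mixed_scenario(gen)
    table <- sim$table; meta <- sim$meta
  } else {
    table <- read_community_table(config$table_path)
    meta <- list(samples = read_sample_metadata(config$metadata_path),
                 plant_composition = NULL)
    sim <- NULL
  }

  ## filter -> rarefy (fixed order)
  table <- filter_low_count_taxa(table, min_reads = config$min_reads)
  depth_used <- min(config$depth, min(sample_depths(table)))
  table <- rarefy_table(table, depth = depth_used,
                        seed = as.integer(seeds[["rarefy"]]))

  ## classification
  cls <- classify_taxa(table)
  utils::write.table(cls, file.path(config$out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## shared distance structure
  geo <- geographic_distance(meta)
  groups <- covariate_groups()
  covs <- meta$samples[, intersect(unlist(groups), names(meta$samples)), drop = FALSE]
  rownames(covs) <- meta$samples$sample_id
  pruned <- collinearity_prune(covs, threshold = 0.6)
  env_mats <- lapply(pruned$retained, function(v)
    env_distance(covs[, v, drop = FALSE]))
  names(env_mats) <- pruned$retained

  results <- list(classification = cls, pruned = pruned, table = table,
                  meta = meta, subcommunities = list())
  for (sub in config$subcommunities) {
    taxa <- cls$taxon_id[cls$regional_label == sub]
    if (length(taxa) < 2) {
      warning("subcommunity '", sub, "' has fewer than 2 taxa; skipped")
      next
    }
    sdir <- file.path(config$out_dir, sub)
    dir.create(sdir, showWarnings = FALSE)
    st <- subset_community(table, taxa = taxa)
    res <- list()

    ## niche breadth
    b <- levins_b_all(st)
    bcom <- suppressWarnings(community_bcom(st, b))
    utils::write.table(data.frame(taxon_id = names(b), B = unname(b)),
                       file.path(sdir, "levins_b.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = names(bcom), Bcom = unname(bcom)),
                       file.path(sdir, "bcom.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$bcom <- bcom

    ## beta-deviation
    keep <- rowSums(st$counts) > 0
    st2 <- if (all(keep)) st else
      subset_community(st, samples = rownames(st$counts)[keep])
    bd <- beta_deviation(st2, reps = config$reps,
                         seed = as.integer(seeds[["nulldev"]]))
    utils::write.csv(as.data.frame(bd), file.path(sdir, "beta_deviation.csv"),
                     row.names = FALSE)
    res$beta_deviation <- bd

    ## neutral model
    ncm <- tryCatch(fit_ncm(st, N = depth_used), error = function(e) e)
    if (!inherits(ncm, "error")) {
      jsonlite::write_json(list(m = ncm$m, r2 = ncm$r2, N = ncm$N, d = ncm$d,
                                n_taxa = ncm$n_taxa),
                           file.path(sdir, "ncm.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(ncm$taxa, file.path(sdir, "ncm_taxa.csv"), row.names = FALSE)
    }
    res$ncm <- ncm

    ## beta diversity, DDR, PERMANOVA
    bc <- bray_curtis(st2)
    geo_s <- geo[rownames(bc), rownames(bc)]
    ddr <- ddr_fit(bc, geo_s, permutations = config$permutations,
                   seed = as.integer(seeds[["ddr"]]))
    jsonlite::write_json(unclass(ddr), file.path(sdir, "ddr.json"),
                         auto_unbox = TRUE, digits = NA)
    res$ddr <- ddr
    veg <- meta$samples$vegetation_type[match(rownames(bc), meta$samples$sample_id)]
    res$permanova <- tryCatch(
      permanova(bc, veg, permutations = config$permutations,
                seed = as.integer(seeds[["perm"]])),
      error = function(e) e)

    ## MRM + VPA + HP on beta-deviations; samples whose pairs have
    ## undefined deviations (zero null SD) are dropped greedily
    dev_m <- deviation_matrix(bd)
    while (anyNA(dev_m)) {
      worst <- which.max(rowSums(is.na(dev_m)))
      dev_m <- dev_m[-worst, -worst, drop = FALSE]
    }
    lbl <- rownames(dev_m)
    space_set <- list(geo = geo[lbl, lbl])
    env_set <- lapply(env_mats, function(m) m[lbl, lbl])
    fs_env <- forward_select(dev_m, env_set, alpha = config$alpha,
                             permutations = config$permutations,
                             seed = as.integer(seeds[["mrm"]]))
    if (length(fs_env$selected)) {
      vpa <- vpa_two_sets(dev_m, space_set, env_set[fs_env$selected])
    } else {
      # no environmental predictor survives forward selection: no
      # env-attributable variance
      lt0 <- lower.tri(dev_m)
      r2_sp <- ols_r2(dev_m[lt0], vapply(space_set, function(m) m[lt0],
                                         numeric(sum(lt0))))
      vpa <- structure(list(pure_space = r2_sp, pure_env = 0, shared = 0,
                            unexplained = 1 - r2_sp, r2_full = r2_sp,
                            r2_space = r2_sp, r2_env = 0),
                       class = "vpa_result")
    }
    jsonlite::write_json(unclass(vpa), file.path(sdir, "vpa.json"),
                         auto_unbox = TRUE, digits = NA)
    res$forward_selection <- fs_env
    res$vpa <- vpa

    hp_groups <- lapply(covariate_groups(), function(vars) {
      vars <- intersect(vars, names(env_set))
      env_set[vars]
    })
    hp_groups <- hp_groups[vapply(hp_groups, length, integer(1)) > 0]
    hp_groups$space <- space_set
    hp <- hierarchical_partition(dev_m, hp_groups)
    jsonlite::write_json(list(contributions = as.list(hp$contributions),
                              r2_full = hp$r2_full),
                         file.path(sdir, "hp.json"), auto_unbox = TRUE, digits = NA)
    res$hp <- hp

    ## path analysis
    gm <- covariate_groups()
    grp_dist <- function(vars) {
      vars <- intersect(vars, pruned$retained)
      if (!length(vars)) return(NULL)
      env_distance(covs[lbl, vars, drop = FALSE])
    }
    vars <- list(space = geo[lbl, lbl],
                 soil = grp_dist(gm$soil),
                 climate = grp_dist(gm$climate),
                 plant = grp_dist(gm$plant),
                 fungal_deviation = dev_m)
    vars <- vars[!vapply(vars, is.null, logical(1))]
    mediators <- setdiff(names(vars), c("space", "fungal_deviation"))
    if (length(mediators)) {
      # space drives each surviving mediator group; all of them plus
      # space's direct edge drive the fungal deviation
      edges <- rbind(data.frame(from = "space", to = mediators),
                     data.frame(from = c(mediators, "space"),
                                to = "fungal_deviation"))
      pd <- lapply(vars, function(m) m[lower.tri(m)])
      pfit <- fit_path_model(path_spec(edges), as.data.frame(pd))
      jsonlite::write_json(list(r2_outcome = pfit$r2_outcome,
                                effects = pfit$effects,
                                coefficients = pfit$coefficients),
                           file.path(sdir, "path.json"),
                           auto_unbox = TRUE, digits = NA)
      res$path <- pfit
    }
    results$subcommunities[[sub]] <- res
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fungalassembly")),
    config = config[setdiff(names(config), "out_dir")],
    stage_seeds = as.list(seeds),
    pruned_covariates = pruned$dropped,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(results)
}
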