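#' Configuration for the synthetic metacommunity generator
#'
#' Defaults emulate a 30-site desert transect design: 3 quadrat samples
#' per site (90 samples), four vegetation types, a lognormal
#' species-abundance distribution in which a small abundant fraction
#' holds most reads, and a per-sample sequencing depth of 9,080 reads.
#' The process knobs map one-to-one onto assembly mechanisms:
#' `selection_strength` x environmental heterogeneity is heterogeneous
#' selection, `dispersal_decay_km` is dispersal limitation
#' (`Inf` disables it), and `m_immigration` is neutral immigration/drift.
#'
#' @param n_sites number of sites along the transect (default 30)
#' @param quadrats_per_site samples per site (default 3)
#' @param n_taxa taxa in the regional pool (default 1000)
#' @param depth reads per sample (default 9080)
#' @param sad_meanlog,sad_sdlog lognormal species-abundance parameters
#'   (defaults 0 and 2.5: a small abundant minority holds most reads)
#' @param selection_strength Gaussian niche-filtering intensity (>= 0;
#'   0 = neutral)
#' @param niche_sd niche breadth of taxa along the latent environmental
#'   axis (default 0.4; the realized axis spans roughly 5 units)
#' @param m_immigration neutral immigration rate in (0, 1] (default 0.05;
#'   1 is the pure mass-effect limit with no local drift)
#' @param dispersal_decay_km dispersal kernel scale; `Inf` = no distance
#'   limitation
#' @param env_spatial_corr correlation of environment with the spatial
#'   gradient, in `[0, 1]` (default 0.7)
#' @param n_veg_types vegetation classes cut from the latent gradient
#'   (default 4)
#' @param transect_km transect length (default 2500)
#' @param seed integer seed (default 1)
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_sites = 30, quadrats_per_site = 3, n_taxa = 1000,
                       depth = 9080, sad_meanlog = 0, sad_sdlog = 2.5,
                       selection_strength = 0, niche_sd = 0.4,
                       m_immigration = 0.05, dispersal_decay_km = Inf,
                       env_spatial_corr = 0.7, n_veg_types = 4,
                       transect_km = 2500, seed = 1) {
  cfg <- list(n_sites = n_sites, quadrats_per_site = quadrats_per_site,
              n_taxa = n_taxa, depth = depth, sad_meanlog = sad_meanlog,
              sad_sdlog = sad_sdlog, selection_strength = selection_strength,
              niche_sd = niche_sd, m_immigration = m_immigration,
              dispersal_decay_km = dispersal_decay_km,
              env_spatial_corr = env_spatial_corr, n_veg_types = n_veg_types,
              transect_km = transect_km, seed = seed)
  stopifnot(cfg$n_sites >= 2, cfg$quadrats_per_site >= 1, cfg$n_taxa >= 2,
            cfg$depth >= 1, cfg$selection_strength >= 0, cfg$niche_sd > 0,
            cfg$m_immigration > 0, cfg$m_immigration <= 1,
            cfg$dispersal_decay_km > 0,
            cfg$env_spatial_corr >= 0, cfg$env_spatial_corr <= 1,
            cfg$n_veg_types >= 1)
  class(cfg) <- "sim_config"
  cfg
}

# site-level covariate loading on the shared environmental axis, with an
# affine map to field-realistic units; loading ~0.75 keeps pairwise
# covariate correlations below typical pruning thresholds while each
# covariate still tracks the axis
env_covariate <- function(env_axis, center, spread, loading = 0.75) {
  n <- length(env_axis)
  z <- loading * env_axis + sqrt(1 - loading^2) * stats::rnorm(n)
  center + spread * z
}

#' Simulate transect covariates and sample metadata
#'
#' Sites are placed along a transect (default ~2,500 km) at desert
#' latitudes; each site contributes `quadrats_per_site` samples jittered
#' by a few hundred metres. Soil, climate and plant covariates are noisy
#' affine images of a latent spatial gradient, with the
#' environment-space correlation set by `env_spatial_corr`. Vegetation
#' type is assigned by thresholding a noisy copy of the gradient into
#' `n_veg_types` classes. A plant community composition table (Gaussian
#' niches on the gradient) is generated alongside.
#'
#' @param cfg a [sim_config()]
#' @return list of class `sample_metadata`: `samples` (data.frame with
#'   sample_id, site_id, lat, lon, vegetation_type, gradient and the
#'   soil/climate/plant covariates) and `plant_composition`
#'   (samples x plant-species abundance matrix)
#' @export
simulate_covariates <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_sites; q <- cfg$quadrats_per_site
  pos <- sort(stats::runif(ns, 0, cfg$transect_km))
  g_site <- as.numeric(scale(pos))
  rho <- cfg$env_spatial_corr
  # one shared latent environmental axis: rho-correlated with space, the
  # rest locally determined; niche selection operates on this axis
  e_site <- rho * g_site + sqrt(1 - rho^2) * stats::rnorm(ns)

  # site-level covariates on field-realistic scales
  site_env <- data.frame(
    SM  = env_covariate(e_site, 3.0, 1.2),     # soil moisture %
    pH  = env_covariate(e_site, 8.2, 0.4),
    TSN = env_covariate(e_site, 0.45, 0.15),   # g/kg
    SAN = env_covariate(e_site, 22, 8),        # mg/kg
    TSP = env_covariate(e_site, 0.55, 0.12),   # g/kg
    TOC = env_covariate(e_site, 4.5, 1.6),     # g/kg
    MAT = env_covariate(e_site, 5.6, 2.6),     # deg C
    PET = env_covariate(e_site, 1450, 140),    # mm
    PLC = env_covariate(e_site, 30, 9),        # plant cover %
    SLA = env_covariate(e_site, 10.5, 2.4),
    LCN = env_covariate(e_site, 26, 5),
    LNP = env_covariate(e_site, 12.5, 2.6),
    PHight = env_covariate(e_site, 1.1, 0.35),
    Cwidth = env_covariate(e_site, 1.6, 0.5)
  )
  ai_raw <- 0.17 + 0.075 * (0.75 * e_site + sqrt(1 - 0.75^2) * stats::rnorm(ns))
  site_env$MAP <- pmin(pmax(ai_raw, 0.03), 0.32) * site_env$PET
  site_env$richness <- pmax(1, round(env_covariate(e_site, 8, 2.5)))
  veg_latent <- 0.85 * e_site + sqrt(1 - 0.85^2) * stats::rnorm(ns)
  veg_labels <- if (cfg$n_veg_types <= 4)
    c("SHD", "SHSD", "HSPD", "DSAD")[seq_len(cfg$n_veg_types)]
  else sprintf("VT%d", seq_len(cfg$n_veg_types))
  veg <- cut(veg_latent,
             breaks = stats::quantile(veg_latent,
                                      probs = seq(0, 1, length.out = cfg$n_veg_types + 1)),
             labels = veg_labels,
             include.lowest = TRUE)

  # expand to quadrat samples with small within-site jitter
  idx <- rep(seq_len(ns), each = q)
  km_per_deg_lon <- 111.195 * cos(40 * pi / 180)
  jitter_km <- stats::runif(ns * q, -0.15, 0.15) + rep(seq_len(q) * 0.3, times = ns)
  samples <- data.frame(
    sample_id = sprintf("S%02dQ%d", idx, rep(seq_len(q), times = ns)),
    site_id = sprintf("S%02d", idx),
    lat = 40 + stats::rnorm(ns * q, 0, 0.001),
    lon = 75 + (pos[idx] + jitter_km) / km_per_deg_lon,
    vegetation_type = as.character(veg)[idx],
    gradient = g_site[idx] + stats::rnorm(ns * q, 0, 0.05),
    env_axis = e_site[idx] + stats::rnorm(ns * q, 0, 0.05),
    stringsAsFactors = FALSE
  )
  for (v in names(site_env))
    samples[[v]] <- site_env[[v]][idx] * (1 + stats::rnorm(ns * q, 0, 0.03))
  samples$richness <- pmax(1, round(samples$richness))
  samples$aridity <- derive_aridity(samples$MAP, samples$PET)

  # plant community: Gaussian niches for 40 plant species on the gradient
  n_plants <- 40
  popt <- stats::runif(n_plants, min(samples$env_axis), max(samples$env_axis))
  psize <- stats::rlnorm(n_plants, 2, 1)
  lam <- outer(samples$env_axis, popt, function(g, o)
    exp(-(g - o)^2 / (2 * 0.35^2)))
  lam <- sweep(lam, 2, psize, "*")
  plant <- matrix(stats::rpois(length(lam), lam), nrow(lam),
                  dimnames = list(samples$sample_id,
                                  sprintf("plant%02d", seq_len(n_plants))))
  structure(list(samples = samples, plant_composition = plant),
            class = "sample_metadata")
}

# expected (unnormalized) composition per sample given process knobs;
# rows samples, cols taxa
expected_composition <- function(cfg, meta, pool, optima, home_site_pos) {
  g <- meta$samples$env_axis
  E <- matrix(rep(pool, each = length(g)), length(g), length(pool))
  if (cfg$selection_strength > 0) {
    niche <- outer(g, optima, function(gg, oo)
      exp(-(gg - oo)^2 / (2 * cfg$niche_sd^2)))
    E <- E * niche^cfg$selection_strength
  }
  if (is.finite(cfg$dispersal_decay_km) && !is.null(home_site_pos)) {
    km_per_deg_lon <- 111.195 * cos(40 * pi / 180)
    sample_pos <- (meta$samples$lon - 75) * km_per_deg_lon
    dk <- outer(sample_pos, home_site_pos, function(a, b) abs(a - b))
    E <- E * exp(-dk / cfg$dispersal_decay_km)
  }
  E
}

# Dirichlet-multinomial realization of local communities: local relative
# abundances drift around the expected composition with concentration
# depth * m / (1 - m), so m -> 1 is the pure mass-effect limit (local
# sampling directly from the pool, no drift) and small m gives strong
# drift, matching the Sloan neutral marginal up to the m/(1-m) scale
realize_counts <- function(cfg, E, sample_ids) {
  En <- E / rowSums(E)
  m <- cfg$m_immigration
  if (m >= 1) {
    theta <- En
  } else {
    alpha <- cfg$depth * (m / (1 - m)) * En
    theta <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow(alpha))
    bad <- rowSums(theta) == 0
    if (any(bad)) theta[bad, ] <- En[bad, ]
  }
  cnt <- t(apply(theta, 1, function(th) stats::rmultinom(1, cfg$depth, th)[, 1]))
  dimnames(cnt) <- list(sample_ids, sprintf("ASV%04d", seq_len(ncol(E))))
  community_table(cnt)
}

#' Simulate a metacommunity under configured assembly processes
#'
#' Regional pool abundances follow the configured lognormal SAD. Each
#' sample's expected composition is the pool filtered by a Gaussian
#' environmental niche factor (raised to `selection_strength`) and by an
#' exponential dispersal kernel around each taxon's home site; local
#' communities are then realized with Dirichlet-multinomial drift whose
#' concentration is `depth * m_immigration` (the Sloan neutral marginal
#' when selection and dispersal limitation are switched off). Every
#' sample receives exactly `depth` reads.
#'
#' @param cfg a [sim_config()]
#' @param meta matching [simulate_covariates()] output; generated from
#'   `cfg` when `NULL`
#' @return list of class `sim_community`: `table` (a
#'   [community_table()]), `meta`, `pool`, `optima`
#' @export
simulate_metacommunity <- function(cfg, meta = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(meta)) meta <- simulate_covariates(cfg)
  set.seed(cfg$seed + 1L)
  pool <- stats::rlnorm(cfg$n_taxa, cfg$sad_meanlog, cfg$sad_sdlog)
  g <- meta$samples$env_axis
  optima <- stats::runif(cfg$n_taxa, min(g), max(g))
  km_per_deg_lon <- 111.195 * cos(40 * pi / 180)
  sample_pos <- (meta$samples$lon - 75) * km_per_deg_lon
  home <- sample(sample_pos, cfg$n_taxa, replace = TRUE, prob = NULL)
  E <- expected_composition(cfg, meta, pool, optima, home)
  tab <- realize_counts(cfg, E, meta$samples$sample_id)
  structure(list(table = tab, meta = meta, pool = pool, optima = optima),
            class = "sim_community")
}

#' Mixed-scenario metacommunity: neutral abundant tail, selected rare tail
#'
#' Builds the headline contrast of the analysis: the abundant tail of
#' the species-abundance distribution (top decile of pool abundance)
#' assembles neutrally with unlimited dispersal, while the remaining
#' (rare) taxa experience strong Gaussian niche selection along the
#' environmental gradient. Downstream, the neutral model should fit the
#' abundant subcommunity better than the rare one, community niche
#' breadth should be higher for abundant taxa, and environment should
#' explain more of the rare beta-deviations.
#'
#' @param cfg a [sim_config()]; its `selection_strength` (default 6 if
#'   left at 0) applies to the rare tail only
#' @param meta optional matching metadata
#' @return list of class `sim_community` with extra elements
#'   `neutral_taxa` and `selected_taxa` (taxon IDs)
#' @export
mixed_scenario <- function(cfg = sim_config(), meta = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$selection_strength == 0) cfg$selection_strength <- 6
  if (is.null(meta)) meta <- simulate_covariates(cfg)
  set.seed(cfg$seed + 2L)
  pool <- stats::rlnorm(cfg$n_taxa, cfg$sad_meanlog, cfg$sad_sdlog)
  g <- meta$samples$env_axis
  optima <- stats::runif(cfg$n_taxa, min(g), max(g))
  neutral <- rank(-pool) <= ceiling(0.1 * cfg$n_taxa)

  cfg_neu <- cfg; cfg_neu$selection_strength <- 0; cfg_neu$dispersal_decay_km <- Inf
  E <- expected_composition(cfg_neu, meta, pool, optima, NULL)
  sel <- expected_composition(cfg, meta, pool, optima, home_site_pos = NULL)
  E[, !neutral] <- sel[, !neutral]
  # selection shapes composition within the rare block without
  # transferring its biomass to the abundant block: each block keeps its
  # regional pool share of every sample's expected mass
  share_neutral <- sum(pool[neutral]) / sum(pool)
  E[, neutral] <- E[, neutral] / rowSums(E[, neutral, drop = FALSE]) * share_neutral
  E[, !neutral] <- E[, !neutral] / rowSums(E[, !neutral, drop = FALSE]) * (1 - share_neutral)
  # drift belongs to the neutral process only: the neutral block drifts
  # with concentration depth * m/(1-m) while the selected block follows
  # its niche-determined expectation deterministically
  theta <- E
  m <- cfg$m_immigration
  if (m < 1) {
    alpha <- cfg$depth * (m / (1 - m)) * E[, neutral, drop = FALSE]
    th_n <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow(alpha))
    sums <- rowSums(th_n)
    bad <- sums == 0
    if (any(bad)) { th_n[bad, ] <- E[bad, neutral]; sums[bad] <- rowSums(th_n[bad, , drop = FALSE]) }
    theta[, neutral] <- th_n / sums * share_neutral
  }
  cnt <- t(apply(theta, 1, function(th) stats::rmultinom(1, cfg$depth, th)[, 1]))
  dimnames(cnt) <- list(meta$samples$sample_id, sprintf("ASV%04d", seq_len(cfg$n_taxa)))
  tab <- community_table(cnt)
  structure(list(table = tab, meta = meta, pool = pool, optima = optima,
                 neutral_taxa = colnames(tab$counts)[neutral],
                 selected_taxa = colnames(tab$counts)[!neutral]),
            class = "sim_community")
}
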