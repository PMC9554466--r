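#' @keywords internal
assert_dist_matrix <- function(m, kind = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix not symmetric", call. = FALSE)
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (is.null(rownames(m))) stop("distance matrix must carry sample labels", call. = FALSE)
  if (!is.null(kind)) attr(m, "kind") <- kind
  m
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y)), computed with
#' `vegan::vegdist`. Adding all-zero taxa leaves the matrix unchanged.
#'
#' @param table a [community_table()] with no zero-depth sample
#' @return symmetric samples x samples matrix in `[0, 1]` with zero
#'   diagonal; attribute `kind = "bray_curtis"`
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "community_table"))
  d <- sample_depths(table)
  if (any(d == 0))
    stop("zero-depth sample(s): ", paste(names(d)[d == 0], collapse = ", "), call. = FALSE)
  m <- as.matrix(vegan::vegdist(table$counts, method = "bray"))
  assert_dist_matrix(m, "bray_curtis")
}

#' Great-circle geographic distances (km)
#'
#' Haversine distance on a sphere of radius 6371 km between every pair of
#' samples.
#'
#' @param meta data.frame with columns `sample_id`, `lat`, `lon` (decimal
#'   degrees), or the `$samples` element of [simulate_covariates()]
#' @return symmetric matrix of pairwise distances in km, labeled by
#'   `sample_id`; attribute `kind = "geographic_km"`
#' @export
geographic_distance <- function(meta) {
  if (is.list(meta) && !is.data.frame(meta) && !is.null(meta$samples)) meta <- meta$samples
  req <- c("sample_id", "lat", "lon")
  if (!all(req %in% names(meta)))
    stop("metadata must have columns sample_id, lat, lon", call. = FALSE)
  bad <- meta$sample_id[is.na(meta$lat) | is.na(meta$lon)]
  if (length(bad))
    stop("missing coordinates for sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  pts <- cbind(meta$lon, meta$lat)
  m <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(m) <- list(meta$sample_id, meta$sample_id)
  diag(m) <- 0
  assert_dist_matrix((m + t(m)) / 2, "geographic_km")
}

#' Standardized environmental Euclidean distance
#'
#' Each covariate is z-scored (mean 0, SD 1 across samples) before the
#' Euclidean distance is taken, so the matrix is invariant to the
#' covariates' units.
#'
#' @param covariates numeric matrix or data.frame (samples x covariates)
#'   with sample IDs as rownames
#' @return symmetric distance matrix; attribute `kind = "env_euclidean"`
#' @export
env_distance <- function(covariates) {
  x <- as.matrix(covariates)
  if (ncol(x) < 1) stop("need >= 1 covariate", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance covariate(s) cannot be standardized: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  m <- as.matrix(stats::dist(scale(x)))
  assert_dist_matrix(m, "env_euclidean")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the unfolded lower triangles; significance by
#' jointly permuting the rows and columns of the second matrix. The
#' p-value is two-sided with the +1 correction:
#' p = (#\{|r_perm| >= |r_obs|\} + 1) / (permutations + 1).
#'
#' @param a,b distance matrices with identical sample labels (n >= 4)
#' @param permutations number of label permutations (default 999)
#' @param seed optional integer seed
#' @return list with `r`, `p`, `permutations`
#' @export
mantel_test <- function(a, b, permutations = 999, seed = NULL) {
  assert_dist_matrix(a); assert_dist_matrix(b)
  if (!identical(rownames(a), rownames(b)))
    stop("sample labels of the two matrices do not match", call. = FALSE)
  n <- nrow(a)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  lt <- lower.tri(a)
  va <- a[lt]
  r_obs <- stats::cor(va, b[lt])
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(permutations), function(i) {
    idx <- sample.int(n)
    stats::cor(va, b[idx, idx][lt])
  }, numeric(1))
  p <- (sum(abs(r_perm) >= abs(r_obs)) + 1) / (permutations + 1)
  list(r = r_obs, p = p, permutations = permutations)
}

#' PERMANOVA of a distance matrix across groups
#'
#' Wraps `vegan::adonis2` (pseudo-F from among/within sums of squared
#' distances; p by label permutation).
#'
#' @param d distance matrix
#' @param groups factor-like grouping aligned with the matrix labels;
#'   >= 2 groups, each with >= 2 members
#' @param permutations number of permutations (default 999)
#' @param seed optional integer seed
#' @return list with `pseudo_F`, `R2`, `p`, `permutations`
#' @export
permanova <- function(d, groups, permutations = 999, seed = NULL) {
  assert_dist_matrix(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(groups = groups)
  fit <- vegan::adonis2(stats::as.dist(d) ~ groups, data = df,
                        permutations = permutations)
  list(pseudo_F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1],
       permutations = permutations)
}

#' Distance-decay regression of community similarity
#'
#' Ordinary least squares of compositional similarity (1 - Bray-Curtis)
#' against geographic distance over all sample pairs (lower triangle).
#' The slope is the turnover rate per km. Because pairs are not
#' independent, a Mantel-style permutation p-value (permuting the
#' similarity matrix's sample labels) is reported alongside the naive
#' OLS p.
#'
#' @param beta Bray-Curtis dissimilarity matrix
#' @param geo geographic distance matrix (km), same labels
#' @param permutations permutations for the permutation p (default 999)
#' @param seed optional integer seed
#' @return list of class `ddr_fit`: `slope` (per km), `slope_per_1000km`,
#'   `intercept`, `r2`, `p_ols`, `p_perm`, `n_pairs`
#' @export
ddr_fit <- function(beta, geo, permutations = 999, seed = NULL) {
  assert_dist_matrix(beta); assert_dist_matrix(geo)
  if (!identical(rownames(beta), rownames(geo)))
    stop("sample labels do not match", call. = FALSE)
  lt <- lower.tri(beta)
  sim <- 1 - beta[lt]
  dist_km <- geo[lt]
  if (length(sim) < 3) stop("need >= 3 sample pairs", call. = FALSE)
  if (stats::sd(dist_km) == 0) stop("zero variance in geographic distance", call. = FALSE)
  fit <- stats::lm(sim ~ dist_km)
  slope <- unname(stats::coef(fit)[2])
  sm <- summary(fit)
  n <- nrow(beta)
  if (!is.null(seed)) set.seed(seed)
  slope_perm <- vapply(seq_len(permutations), function(i) {
    idx <- sample.int(n)
    sp <- 1 - beta[idx, idx][lt]
    stats::cov(sp, dist_km) / stats::var(dist_km)
  }, numeric(1))
  p_perm <- (sum(abs(slope_perm) >= abs(slope)) + 1) / (permutations + 1)
  structure(list(slope = slope,
                 slope_per_1000km = slope * 1000,
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_ols = sm$coefficients[2, 4],
                 p_perm = p_perm,
                 n_pairs = length(sim)),
            class = "ddr_fit")
}

#' @export
print.ddr_fit <- function(x, ...) {
  cat("distance-decay regression over", x$n_pairs, "pairs\n")
  cat(sprintf("  slope %.3g per km (%.3g per 1000 km), r2 %.3f, p_ols %.3g, p_perm %.3g\n",
              x$slope, x$slope_per_1000km, x$r2, x$p_ols, x$p_perm))
  invisible(x)
}

#' 2-D NMDS ordination coordinates
#'
#' Thin wrapper over `vegan::metaMDS` emitting the coordinate table and
#' stress for diagnostic ordination of a dissimilarity matrix.
#'
#' @param d distance matrix
#' @param k dimensions (default 2)
#' @param seed optional integer seed
#' @return list with `points` (samples x k matrix) and `stress`
#' @export
nmds_coords <- function(d, k = 2, seed = NULL) {
  assert_dist_matrix(d)
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(d), k = k, trace = 0)
  list(points = fit$points, stress = fit$stress)
}
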