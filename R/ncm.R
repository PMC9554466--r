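#' Expected occurrence frequency under the Sloan neutral model
#'
#' For a taxon with mean relative abundance p in the source pool, the
#' neutral expectation of its local relative abundance is
#' Beta(N*m*p, N*m*(1-p)), where N is the local community size (reads at
#' the rarefied depth) and m the migration rate. The taxon is detected
#' when its local proportion exceeds the detection limit d, so
#' freq(p) = 1 - I_d(N*m*p, N*m*(1-p)), the complement of the regularized
#' incomplete beta function at d. Monotone non-decreasing in p.
#'
#' @param p mean relative abundance(s), each in (0, 1)
#' @param N community size in reads (>= 1)
#' @param m migration rate in (0, 1]
#' @param d detection limit in (0, 1); default one read, 1/N
#' @return expected occurrence frequency, same length as `p`
#' @export
sloan_expected_frequency <- function(p, N, m, d = 1 / N) {
  if (any(p <= 0 | p >= 1)) stop("`p` must lie in (0, 1)", call. = FALSE)
  if (N < 1) stop("`N` must be >= 1", call. = FALSE)
  if (m <= 0 || m > 1) stop("`m` must lie in (0, 1]", call. = FALSE)
  if (d <= 0 || d >= 1) stop("`d` must lie in (0, 1)", call. = FALSE)
  1 - stats::pbeta(d, N * m * p, N * m * (1 - p))
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration rate m by least squares between observed
#' occurrence frequencies (fraction of samples with count > 0) and the
#' neutral expectation [sloan_expected_frequency()] evaluated at each
#' taxon's mean relative abundance. R-squared is computed on the
#' untransformed frequencies and may be negative when the neutral curve
#' fits worse than the mean frequency. 95% binomial prediction bounds
#' around the fitted curve are attached for classifying taxa as
#' above/below the neutral prediction.
#'
#' @param table a rarefied [community_table()] (all sample depths equal),
#'   or a subcommunity subset of one when `N` is supplied
#' @param d detection limit; default 1/N
#' @param N community size in reads. Defaults to the table's common
#'   depth, in which case unequal depths are an error (rarefy first).
#'   When fitting a subcommunity of a rarefied table, pass the
#'   rarefaction depth of the full table: per-taxon mean relative
#'   abundances are then computed against that metacommunity size, as is
#'   conventional for subcommunity neutral-model fits.
#' @return object of class `ncm_fit`: list with `m`, `N`, `d`, `r2`,
#'   `n_taxa`, `n_samples` and `taxa` (per-taxon data.frame: `taxon_id`,
#'   `p`, `freq_obs`, `freq_pred`, `bound_lo`, `bound_hi`)
#' @export
fit_ncm <- function(table, d = NULL, N = NULL) {
  stopifnot(inherits(table, "community_table"))
  depths <- sample_depths(table)
  if (is.null(N)) {
    if (length(unique(depths)) != 1L)
      stop("unequal sample depths: rarefy the table first, or pass `N`",
           call. = FALSE)
    N <- depths[[1]]
  }
  if (is.null(d)) d <- 1 / N
  cnt <- table$counts
  S <- nrow(cnt)
  p <- colMeans(cnt) / N
  freq <- colMeans(cnt > 0)
  keep <- p > 0
  p <- p[keep]; freq <- freq[keep]
  interior <- freq > 0 & freq < 1
  if (sum(interior) < 10)
    stop("degenerate occupancy: fewer than 10 taxa with interior occurrence frequency",
         call. = FALSE)
  ss <- function(m) sum((freq - sloan_expected_frequency(p, N, m, d))^2)
  # bounded scalar least squares with multi-start to dodge local minima
  starts <- c(0.01, 0.1, 0.5)
  fits <- lapply(starts, function(s)
    stats::nlminb(s, ss, lower = 1e-6, upper = 1,
                  control = list(abs.tol = 1e-12, rel.tol = 1e-10)))
  opt <- stats::optimize(ss, c(1e-6, 1), tol = 1e-8)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  m_hat <- if (opt$objective < best$objective) opt$minimum else best$par
  pred <- sloan_expected_frequency(p, N, m_hat, d)
  r2 <- 1 - sum((freq - pred)^2) / sum((freq - mean(freq))^2)
  if (r2 < 0.3)
    warning("neutral model R2 = ", signif(r2, 3),
            " < 0.3: the migration-rate estimate is unreliable")
  lo <- stats::qbinom(0.025, S, pred) / S
  hi <- stats::qbinom(0.975, S, pred) / S
  structure(list(m = m_hat, N = unname(N), d = d, r2 = r2,
                 n_taxa = length(p), n_samples = S,
                 taxa = data.frame(taxon_id = names(p), p = unname(p),
                                   freq_obs = unname(freq),
                                   freq_pred = unname(pred),
                                   bound_lo = unname(lo), bound_hi = unname(hi),
                                   stringsAsFactors = FALSE)),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model fit: m = %.3f, R2 = %.3f (N = %d reads, %d taxa, %d samples)\n",
              x$m, x$r2, as.integer(x$N), x$n_taxa, x$n_samples))
  invisible(x)
}

#' Simulate a community directly from the Sloan neutral model
#'
#' Pool relative abundances follow a lognormal species-abundance
#' distribution. Each sample's local proportion of each taxon is drawn
#' from the model's Beta(N*m*p, N*m*(1-p)) marginal; the taxon is present
#' when that proportion exceeds the detection limit 1/N, and present taxa
#' receive binomial read counts (at least one read). Useful as a
#' parameter-recovery oracle for [fit_ncm()].
#'
#' @param n_samples number of samples
#' @param n_taxa number of taxa in the pool
#' @param depth community size N (reads)
#' @param m migration rate in (0, 1]
#' @param sad_meanlog,sad_sdlog lognormal SAD parameters
#' @param seed optional integer seed
#' @return a [community_table()]; row sums are close to but not exactly
#'   `depth` (occurrence, not depth, is the modeled quantity)
#' @export
simulate_sloan_community <- function(n_samples, n_taxa, depth, m,
                                     sad_meanlog = 0, sad_sdlog = 2,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- stats::rlnorm(n_taxa, sad_meanlog, sad_sdlog)
  p <- pool / sum(pool)
  a <- depth * m * p
  b <- depth * m * (1 - p)
  theta <- matrix(stats::rbeta(n_samples * n_taxa,
                               rep(a, each = n_samples),
                               rep(b, each = n_samples)),
                  n_samples, n_taxa)
  cnt <- matrix(stats::rbinom(n_samples * n_taxa, depth, theta),
                n_samples, n_taxa)
  cnt[theta <= 1 / depth] <- 0
  cnt[theta > 1 / depth & cnt == 0] <- 1
  dimnames(cnt) <- list(sprintf("S%03d", seq_len(n_samples)),
                        sprintf("ASV%04d", seq_len(n_taxa)))
  community_table(cnt)
}
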