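#' One abundance-based null community replicate
#'
#' For each sample independently, individuals are resampled into the local
#' community with probabilities proportional to the regional abundance of
#' each taxon, while the sample's observed species richness and total
#' abundance are kept exactly. Concretely: (a) the sample's observed
#' richness S_k distinct taxa are drawn without replacement from the
#' regional pool with probability proportional to pool abundance; (b) the
#' sample's N_k reads are allocated among the drawn taxa. The default
#' `"seeded"` allocation gives every drawn taxon one read and distributes
#' the remaining N_k - S_k multinomially with pool-proportional
#' probabilities (exact constraint satisfaction, no rejection loop); the
#' `"rejection"` alternative redraws a full multinomial until every drawn
#' taxon has a read, for sensitivity analysis.
#'
#' @param table a [community_table()]; every sample must have richness >= 1
#' @param seed optional integer seed
#' @param method `"seeded"` (default) or `"rejection"` allocation
#' @param pool regional pool abundances (named by taxon). Defaults to the
#'   column sums of `table`; pass the generating pool explicitly when it
#'   is known (e.g. in calibration studies).
#' @return a `community_table` with per-sample richness and totals equal
#'   to the observed ones
#' @export
generate_null_community <- function(table, seed = NULL,
                                    method = c("seeded", "rejection"),
                                    pool = NULL) {
  stopifnot(inherits(table, "community_table"))
  method <- match.arg(method)
  cnt <- table$counts
  if (is.null(pool)) pool <- colSums(cnt)
  if (!is.null(names(pool))) pool <- pool[colnames(cnt)]
  if (anyNA(pool) || length(pool) != ncol(cnt))
    stop("`pool` must cover every taxon in the table", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  taxa <- which(pool > 0)
  pr <- pool[taxa]
  out <- matrix(0, nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
  for (k in seq_len(nrow(cnt))) {
    Sk <- sum(cnt[k, ] > 0)
    Nk <- sum(cnt[k, ])
    if (Sk == 0) stop("sample '", rownames(cnt)[k], "' is empty", call. = FALSE)
    if (Sk > length(taxa))
      stop("sample '", rownames(cnt)[k], "' richness ", Sk,
           " exceeds pool size ", length(taxa), call. = FALSE)
    drawn <- taxa[sample.int(length(taxa), Sk, prob = pr)]
    w <- pool[drawn]
    if (method == "seeded") {
      alloc <- rep(1, Sk)
      if (Nk > Sk) alloc <- alloc + stats::rmultinom(1, Nk - Sk, w)[, 1]
    } else {
      repeat {
        alloc <- stats::rmultinom(1, Nk, w)[, 1]
        if (all(alloc > 0)) break
      }
    }
    out[k, drawn] <- alloc
  }
  community_table(out)
}

#' Standardized beta-deviation of Bray-Curtis beta-diversity
#'
#' Generates `reps` null communities with [generate_null_community()] and,
#' for every sample pair, standardizes the observed Bray-Curtis
#' dissimilarity against the null ensemble:
#' deviation = (beta_obs - mean(beta_null)) / sd(beta_null).
#'
#' Deviations far above zero indicate dispersal limitation or
#' heterogeneous selection; far below zero, homogenizing dispersal or
#' homogeneous selection; near zero, stochastic assembly.
#'
#' Replicate RNG streams are derived from the master seed, so any
#' replicate is reproducible independently of execution order. Note that
#' when the regional pool is estimated from the observed table itself
#' (the default), each sample contributes 1/n of the pool, which imparts
#' a small negative bias of order 1/n to the deviations; pass the true
#' `pool` when it is known.
#'
#' @param table a [community_table()]
#' @param reps null replicates (default 999; must be >= 99)
#' @param seed integer master seed (default 1)
#' @param method allocation mode, see [generate_null_community()]
#' @param pool optional explicit regional pool
#' @return data.frame of class `beta_deviation` with columns `sample_a`,
#'   `sample_b`, `beta_obs`, `null_mean`, `null_sd`, `deviation`;
#'   attributes `reps`, `seed`, `method`. Pairs with zero null SD get
#'   `NA` deviation with a warning.
#' @export
beta_deviation <- function(table, reps = 999, seed = 1,
                           method = c("seeded", "rejection"), pool = NULL) {
  stopifnot(inherits(table, "community_table"))
  method <- match.arg(method)
  if (reps < 99) stop("`reps` must be >= 99", call. = FALSE)
  obs_m <- bray_curtis(table)
  lt <- lower.tri(obs_m)
  obs <- obs_m[lt]
  np <- length(obs)
  set.seed(seed)
  sub_seeds <- sample.int(2147483646L, reps)
  sm <- numeric(np)
  sq <- numeric(np)
  for (r in seq_len(reps)) {
    nt <- generate_null_community(table, seed = sub_seeds[r],
                                  method = method, pool = pool)
    b <- as.matrix(vegan::vegdist(nt$counts, method = "bray"))[lt]
    sm <- sm + b
    sq <- sq + b^2
  }
  mu <- sm / reps
  sd2 <- (sq - reps * mu^2) / (reps - 1)
  # degenerate ensembles produce exact zeros up to streaming round-off
  sd2[sd2 < 1e-14] <- 0
  s <- sqrt(sd2)
  dev <- (obs - mu) / s
  if (any(s == 0)) {
    warning(sum(s == 0), " pair(s) with zero null SD: deviation reported as NA")
    dev[s == 0] <- NA_real_
  }
  idx <- which(lt, arr.ind = TRUE)
  out <- data.frame(sample_a = rownames(obs_m)[idx[, 1]],
                    sample_b = colnames(obs_m)[idx[, 2]],
                    beta_obs = obs, null_mean = mu, null_sd = s,
                    deviation = dev, stringsAsFactors = FALSE)
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  class(out) <- c("beta_deviation", "data.frame")
  out
}

#' Refold a beta-deviation result into a matrix
#'
#' @param bd a [beta_deviation()] result
#' @return symmetric samples x samples matrix of deviations (zero diagonal)
#' @export
deviation_matrix <- function(bd) {
  stopifnot(inherits(bd, "beta_deviation"))
  # lower-triangle order implies: first label is the first sample_b, the
  # rest appear in order as sample_a
  labels <- c(bd$sample_b[1], unique(bd$sample_a))
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  ia <- match(bd$sample_a, labels)
  ib <- match(bd$sample_b, labels)
  m[cbind(ia, ib)] <- bd$deviation
  m[cbind(ib, ia)] <- bd$deviation
  m
}
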