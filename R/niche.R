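#' Levins' niche breadth of a single taxon
#'
#' B = 1 / sum(p_j^2), where p_j is the proportion of the taxon's reads
#' found in sample j. The samples act as the resource states, so B ranges
#' from 1 (all reads in one sample: a point niche) to the number of
#' samples (perfectly even use). Invariant to rescaling the use vector.
#'
#' @param use non-negative abundance vector of one taxon across samples;
#'   at least one entry must be positive
#' @return Levins' B (scalar)
#' @export
levins_b <- function(use) {
  if (any(use < 0) || anyNA(use)) stop("`use` must be non-negative and complete", call. = FALSE)
  s <- sum(use)
  if (s == 0) stop("all-zero use vector: niche breadth undefined", call. = FALSE)
  p <- use / s
  1 / sum(p^2)
}

#' Levins' niche breadth for every taxon in a table
#'
#' @param table a [community_table()]
#' @param level `"sample"` (default) treats each sample as a resource
#'   state; `"site"` first pools quadrat samples by site
#' @param site_ids when `level = "site"`, a vector of site IDs aligned
#'   with the table's samples
#' @return named numeric vector of B values (taxa with zero total reads
#'   get `NA`)
#' @export
levins_b_all <- function(table, level = c("sample", "site"), site_ids = NULL) {
  stopifnot(inherits(table, "community_table"))
  level <- match.arg(level)
  cnt <- table$counts
  if (level == "site") {
    if (is.null(site_ids) || length(site_ids) != nrow(cnt))
      stop("`site_ids` must align with the table's samples", call. = FALSE)
    cnt <- rowsum(cnt, group = site_ids)
  }
  tot <- colSums(cnt)
  b <- rep(NA_real_, ncol(cnt))
  names(b) <- colnames(cnt)
  nz <- tot > 0
  p2 <- colSums(sweep(cnt[, nz, drop = FALSE], 2, tot[nz], "/")^2)
  b[nz] <- 1 / p2
  b
}

#' Abundance-weighted community niche breadth (Bcom)
#'
#' Bcom of a sample is the mean of the per-taxon Levins' B values of the
#' taxa occurring in that sample, weighted by their within-sample relative
#' abundance (weights renormalized over the taxa present). When the
#' analysis is restricted to a subcommunity (the regionally abundant or
#' rare subset), pass the subset table so that weights renormalize over
#' that subset.
#'
#' @param table a [community_table()] (possibly a subcommunity subset)
#' @param b per-taxon Levins' B, named by taxon ID; computed from `table`
#'   via [levins_b_all()] when `NULL`
#' @return named numeric vector of per-sample Bcom. Samples containing no
#'   taxa of the table raise an error when the table is complete; in
#'   subcommunity use they yield `NA` with a warning.
#' @export
community_bcom <- function(table, b = NULL) {
  stopifnot(inherits(table, "community_table"))
  if (is.null(b)) b <- levins_b_all(table)
  cnt <- table$counts
  if (!all(colnames(cnt) %in% names(b)))
    stop("`b` missing values for some taxa", call. = FALSE)
  b <- b[colnames(cnt)]
  out <- rep(NA_real_, nrow(cnt))
  names(out) <- rownames(cnt)
  for (k in seq_len(nrow(cnt))) {
    w <- cnt[k, ]
    present <- w > 0
    if (!any(present)) next
    w <- w[present] / sum(w[present])
    out[k] <- sum(w * b[present])
  }
  if (anyNA(out)) {
    if (all(is.na(out))) stop("every sample is empty", call. = FALSE)
    warning("sample(s) with no taxa present yield NA Bcom: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}
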