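#' Local (within-sample) abundance classification
#'
#' Labels each taxon within each sample by its local relative abundance:
#' above 1% locally abundant, below 0.01% locally rare, in between
#' intermediate. Both inequalities are strict, so boundary values fall to
#' intermediate. Taxa absent from a sample (zero count) carry no local
#' label (`NA`): an undetected taxon has no local abundance to classify.
#'
#' @param rel samples x taxa relative-abundance matrix (rows sum to 1),
#'   from [relative_abundance()]
#' @param abundant local abundant threshold as a proportion (default 0.01,
#'   i.e. 1%)
#' @param rare local rare threshold as a proportion (default 1e-4,
#'   i.e. 0.01%)
#' @return character matrix of the same shape with entries `"abundant"`,
#'   `"rare"`, `"intermediate"` or `NA` (absent)
#' @export
classify_local <- function(rel, abundant = 0.01, rare = 1e-4) {
  stopifnot(is.matrix(rel), rare < abundant)
  lab <- matrix(NA_character_, nrow(rel), ncol(rel), dimnames = dimnames(rel))
  present <- rel > 0
  lab[present] <- "intermediate"
  lab[present & rel > abundant] <- "abundant"
  lab[present & rel < rare] <- "rare"
  lab
}

#' Regional abundance classification
#'
#' A taxon's regional abundance is the unweighted mean of its per-sample
#' relative abundances over all samples (zeros included). Means above 0.1%
#' are regionally abundant, below 0.005% regionally rare, otherwise
#' intermediate; inequalities are strict. The regional abundant and rare
#' subsets are the units of all downstream subcommunity analyses.
#'
#' @param rel samples x taxa relative-abundance matrix (rows sum to 1)
#' @param abundant regional abundant threshold (default 1e-3, i.e. 0.1%)
#' @param rare regional rare threshold (default 5e-5, i.e. 0.005%)
#' @return data.frame with columns `taxon_id`, `mean_rel_abund`,
#'   `regional_label`
#' @export
classify_regional <- function(rel, abundant = 1e-3, rare = 5e-5) {
  stopifnot(is.matrix(rel), rare < abundant)
  mu <- colMeans(rel)
  lab <- rep("intermediate", length(mu))
  lab[mu > abundant] <- "abundant"
  lab[mu < rare] <- "rare"
  data.frame(taxon_id = colnames(rel), mean_rel_abund = unname(mu),
             regional_label = lab, stringsAsFactors = FALSE)
}

#' Per-taxon occupancy
#'
#' @param table a [community_table()]
#' @return named vector: fraction of samples in which each taxon has a
#'   count > 0
#' @export
occupancy <- function(table) {
  stopifnot(inherits(table, "community_table"))
  colMeans(table$counts > 0)
}

#' Full taxon classification table
#'
#' Convenience wrapper combining [classify_regional()] and [occupancy()]
#' on a (typically filtered and rarefied) community table.
#'
#' @inheritParams occupancy
#' @param abundant,rare regional thresholds passed to [classify_regional()]
#' @return data.frame with columns `taxon_id`, `mean_rel_abund`,
#'   `occupancy`, `regional_label`
#' @export
classify_taxa <- function(table, abundant = 1e-3, rare = 5e-5) {
  rel <- relative_abundance(table)
  out <- classify_regional(rel, abundant = abundant, rare = rare)
  out$occupancy <- unname(occupancy(table))[match(out$taxon_id, colnames(rel))]
  out[, c("taxon_id", "mean_rel_abund", "occupancy", "regional_label")]
}
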