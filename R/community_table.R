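#' Construct a validated community table
#'
#' The central data object of the pipeline: a samples x taxa matrix of
#' non-negative integer read counts with unique sample and taxon
#' identifiers. All downstream functions (`classify_regional()`,
#' [beta_deviation()], [fit_ncm()], ...) consume this object.
#'
#' @param counts numeric matrix, samples in rows and taxa in columns, with
#'   unique rownames (sample IDs) and colnames (taxon IDs). All entries must
#'   be non-negative whole numbers.
#' @return An object of class `community_table`: a list with elements
#'   `counts` (integer-valued matrix), `sample_ids`, `taxon_ids`.
#' @examples
#' m <- matrix(c(6, 2, 0, 2, 4, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' ct <- community_table(m)
#' sample_depths(ct)
#' @export
community_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (samples x taxa)", call. = FALSE)
  if (ncol(counts) == 0L) stop("no taxa: community table has zero columns", call. = FALSE)
  if (nrow(counts) == 0L) stop("no samples: community table has zero rows", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry sample IDs as rownames and taxon IDs as colnames", call. = FALSE)
  dup_s <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_s)) stop("duplicate sample ID(s): ", paste(unique(dup_s), collapse = ", "), call. = FALSE)
  dup_t <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_t)) stop("duplicate taxon ID(s): ", paste(unique(dup_t), collapse = ", "), call. = FALSE)
  if (anyNA(counts)) stop("counts contain NA", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be whole numbers", call. = FALSE)
  storage.mode(counts) <- "double"
  counts <- round(counts)
  structure(
    list(counts = counts,
         sample_ids = rownames(counts),
         taxon_ids = colnames(counts)),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  d <- sample_depths(x)
  cat("read depth: min", min(d), "/ median", stats::median(d), "/ max", max(d), "\n")
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

#' Per-sample read totals
#' @param table a [community_table()]
#' @return named numeric vector of row sums (reads per sample)
#' @export
sample_depths <- function(table) {
  stopifnot(inherits(table, "community_table"))
  rowSums(table$counts)
}

#' Subset a community table by taxa and/or samples
#'
#' @param table a [community_table()]
#' @param taxa character vector of taxon IDs to keep (default all)
#' @param samples character vector of sample IDs to keep (default all)
#' @return a `community_table` restricted to the requested IDs, in the
#'   requested order
#' @export
subset_community <- function(table, taxa = NULL, samples = NULL) {
  stopifnot(inherits(table, "community_table"))
  cnt <- table$counts
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, colnames(cnt))
    if (length(missing)) stop("unknown taxon ID(s): ", paste(missing, collapse = ", "), call. = FALSE)
    cnt <- cnt[, taxa, drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(cnt))
    if (length(missing)) stop("unknown sample ID(s): ", paste(missing, collapse = ", "), call. = FALSE)
    cnt <- cnt[samples, , drop = FALSE]
  }
  community_table(cnt)
}

#' Read a community table from TSV or BIOM
#'
#' TSV layout follows common ASV-table exports: taxa as rows, samples as
#' columns, first header token an ID column (e.g. `#ASV ID`, `#OTU ID`).
#' Orientation is auto-detected from that token and can be forced with
#' `taxa_as_rows`. BIOM files (JSON or HDF5 dialect) are read through the
#' biomformat package.
#'
#' @param path file path
#' @param format `"tsv"` or `"biom"`
#' @param taxa_as_rows logical; force the TSV orientation instead of
#'   auto-detecting from the header token. Ignored for BIOM.
#' @return a [community_table()] (samples x taxa)
#' @export
read_community_table <- function(path, format = c("tsv", "biom"), taxa_as_rows = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
    return(community_table(t(m)))
  }
  first <- readLines(path, n = 1L)
  header <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in ", path, ": expected tab-delimited sample IDs", call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate row ID(s) in ", path, ": ", paste(unique(dup), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -1, drop = FALSE], 2, function(col) all(grepl("^\\s*-?\\d+\\s*$", col))))
    stop("non-integer cell(s) in column(s): ",
         paste(colnames(df)[-1][bad], collapse = ", "), call. = FALSE)
  }
  rownames(m) <- ids
  if (is.null(taxa_as_rows)) {
    # common exports put taxa in rows with an '#OTU ID'/'#ASV ID' lead token
    taxa_as_rows <- grepl("^#?\\s*(OTU|ASV)[ _]?ID", header[1], ignore.case = TRUE) ||
      header[1] == "" || !grepl("sample", header[1], ignore.case = TRUE)
  }
  if (taxa_as_rows) m <- t(m)
  community_table(m)
}

#' Write a community table as TSV (taxa as rows)
#'
#' @param table a [community_table()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_community_table <- function(table, path) {
  stopifnot(inherits(table, "community_table"))
  m <- t(table$counts)  # taxa as rows
  df <- data.frame(`#ASV ID` = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Discard taxa with fewer total reads than a threshold
#'
#' Removes ASVs whose summed count across all samples is below `min_reads`,
#' guarding downstream rare-taxon analyses against spurious singletons. The
#' threshold is applied to totals across samples; set `per_sample = TRUE`
#' to instead zero out within-sample counts below the threshold.
#'
#' @param table a [community_table()]
#' @param min_reads integer >= 0; taxa with total reads < `min_reads` are
#'   dropped (default 8)
#' @param per_sample apply the threshold within each sample instead of to
#'   taxon totals
#' @return filtered `community_table`. If no taxa survive, a degenerate
#'   table with zero taxon columns is returned, flagged with attribute
#'   `empty_taxa = TRUE`, and a warning is raised.
#' @export
filter_low_count_taxa <- function(table, min_reads = 8, per_sample = FALSE) {
  stopifnot(inherits(table, "community_table"))
  if (min_reads < 0) stop("`min_reads` must be >= 0", call. = FALSE)
  cnt <- table$counts
  if (per_sample) {
    cnt[cnt < min_reads] <- 0
    keep <- colSums(cnt) > 0
  } else {
    keep <- colSums(cnt) >= min_reads
  }
  if (!any(keep)) {
    warning("all taxa fall below min_reads = ", min_reads, "; returning empty taxon set")
    out <- table
    out$counts <- cnt[, keep, drop = FALSE]
    out$taxon_ids <- character(0)
    attr(out, "empty_taxa") <- TRUE
    return(out)
  }
  community_table(cnt[, keep, drop = FALSE])
}

#' Rarefy every sample to a common read depth
#'
#' Exact subsampling without replacement (multivariate hypergeometric), once
#' per sample; the subsample is deterministic given `seed`. Samples already
#' at the target depth are left untouched.
#'
#' @param table a [community_table()]
#' @param depth target reads per sample (default 9080)
#' @param seed integer seed for the subsampling RNG; `NULL` leaves the RNG
#'   state alone
#' @return a `community_table` in which every row sums to `depth`
#' @export
rarefy_table <- function(table, depth = 9080, seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  d <- sample_depths(table)
  shallow <- names(d)[d < depth]
  if (length(shallow))
    stop("sample(s) shallower than depth ", depth, ": ",
         paste(shallow, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cnt <- table$counts
  out <- cnt
  nt <- ncol(cnt)
  for (k in seq_len(nrow(cnt))) {
    if (d[k] == depth) next
    reads <- rep.int(seq_len(nt), cnt[k, ])
    out[k, ] <- tabulate(sample(reads, depth), nbins = nt)
  }
  community_table(out)
}

#' Relative abundance matrix
#'
#' @param table a [community_table()]
#' @return samples x taxa matrix of proportions; each row sums to 1
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "community_table"))
  d <- sample_depths(table)
  if (any(d == 0))
    stop("zero-depth sample(s): ", paste(names(d)[d == 0], collapse = ", "), call. = FALSE)
  sweep(table$counts, 1, d, "/")
}

#' Aridity from precipitation and potential evapotranspiration
#'
#' Aridity level is one minus the aridity index AI = MAP/PET, so that
#' larger values mean drier sites.
#'
#' @param MAP mean annual precipitation (mm)
#' @param PET annual potential evapotranspiration (mm); must be > 0
#' @return aridity = 1 - MAP/PET (vectorized)
#' @export
derive_aridity <- function(MAP, PET) {
  if (any(PET <= 0)) stop("PET must be > 0", call. = FALSE)
  1 - MAP / PET
}

#' Greedy collinearity pruning of covariates
#'
#' Repeatedly finds the covariate pair with the largest absolute Pearson
#' correlation above `threshold` and drops the member with the higher mean
#' absolute correlation to all remaining covariates, until no pair exceeds
#' the threshold. Columns listed in `keep` are protected (their partner is
#' dropped instead).
#'
#' @param covariates numeric matrix or data.frame, samples x covariates,
#'   with column names
#' @param threshold maximum tolerated |r| (default 0.6)
#' @param keep character vector of column names never to drop
#' @return list with `retained`, `dropped` (in drop order) and `steps`
#'   (data.frame logging each drop: pair, r, victim)
#' @export
collinearity_prune <- function(covariates, threshold = 0.6, keep = character(0)) {
  x <- as.matrix(covariates)
  if (!is.numeric(x) || ncol(x) < 2) stop("need a numeric matrix with >= 2 covariates", call. = FALSE)
  if (nrow(x) < 3) stop("need >= 3 samples to estimate correlations", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s) (undefined correlation): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  dropped <- character(0)
  steps <- list()
  repeat {
    C <- abs(stats::cor(x))
    diag(C) <- 0
    mx <- max(C)
    if (mx <= threshold) break
    idx <- which(C == mx, arr.ind = TRUE)[1, ]
    a <- colnames(x)[idx[1]]; b <- colnames(x)[idx[2]]
    meanabs <- rowMeans(C)
    victim <- if (a %in% keep && b %in% keep) {
      stop("both '", a, "' and '", b, "' are protected but |r| = ",
           signif(mx, 3), " > ", threshold, call. = FALSE)
    } else if (a %in% keep) b
    else if (b %in% keep) a
    else if (meanabs[a] >= meanabs[b]) a else b
    steps[[length(steps) + 1L]] <- data.frame(var_a = a, var_b = b,
                                              r = mx, dropped = victim)
    dropped <- c(dropped, victim)
    x <- x[, setdiff(colnames(x), victim), drop = FALSE]
    if (ncol(x) < 2) break
  }
  list(retained = colnames(x),
       dropped = dropped,
       steps = if (length(steps)) do.call(rbind, steps) else
         data.frame(var_a = character(0), var_b = character(0),
                    r = numeric(0), dropped = character(0)))
}

#' Read sample metadata from CSV
#'
#' Requires columns `sample_id`, `site_id`, `lat`, `lon`, `vegetation_type`;
#' any further numeric columns are treated as environmental/plant
#' covariates.
#'
#' @param path CSV file path
#' @return data.frame with one row per sample
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "site_id", "lat", "lon", "vegetation_type")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("metadata missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  if (any(df$lat < -90 | df$lat > 90)) stop("lat out of [-90, 90]", call. = FALSE)
  if (any(df$lon < -180 | df$lon > 180)) stop("lon out of [-180, 180]", call. = FALSE)
  df
}
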