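#' Unfold a distance matrix into a pairwise vector
#'
#' Lower triangle in column-major order — for a 3x3 matrix the pairs
#' (2,1), (3,1), (3,2) — with the index map kept as attributes so the
#' vector can be refolded.
#'
#' @param d square symmetric matrix with sample labels
#' @return numeric vector of length n(n-1)/2 with attributes `labels`
#'   and `pairs` (two-column index matrix)
#' @export
unfold <- function(d) {
  assert_dist_matrix(d)
  lt <- lower.tri(d)
  v <- d[lt]
  attr(v, "labels") <- rownames(d)
  attr(v, "pairs") <- which(lt, arr.ind = TRUE)
  v
}

#' Refold a pairwise vector into a symmetric matrix
#'
#' Inverse of [unfold()].
#'
#' @param v vector produced by [unfold()] (or any vector plus `labels`)
#' @param labels sample labels; defaults to `attr(v, "labels")`
#' @return symmetric matrix with zero diagonal
#' @export
refold <- function(v, labels = attr(v, "labels")) {
  n <- length(labels)
  if (length(v) != n * (n - 1) / 2) stop("length mismatch", call. = FALSE)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}

# internal: validate a named list of distance matrices against response labels
check_predictors <- function(predictors, labels) {
  if (!length(predictors) || is.null(names(predictors)) || any(names(predictors) == ""))
    stop("`predictors` must be a non-empty named list of distance matrices", call. = FALSE)
  for (nm in names(predictors)) {
    assert_dist_matrix(predictors[[nm]])
    if (!identical(rownames(predictors[[nm]]), labels))
      stop("predictor '", nm, "' labels do not match the response", call. = FALSE)
  }
  invisible(TRUE)
}

# internal: R2 of OLS of y on columns of X (with intercept)
ols_r2 <- function(y, X) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Multiple regression on distance matrices
#'
#' OLS of the unfolded response distance matrix on unfolded predictor
#' matrices. Significance is assessed by jointly permuting the response
#' matrix's sample labels (which preserves the distance-matrix dependence
#' structure, unlike permuting raw pairs) and refitting; p-values carry
#' the +1 correction.
#'
#' @param response distance matrix
#' @param predictors named list of distance matrices with matching labels
#' @param permutations label permutations (default 999)
#' @param seed optional integer seed
#' @return object of class `mrm_fit`: `coefficients` (incl. intercept),
#'   `r2`, `pvals` (per predictor, two-sided on |coef|), `p_model`
#'   (on R2), `permutations`, `n_pairs`
#' @export
mrm_fit <- function(response, predictors, permutations = 999, seed = NULL) {
  assert_dist_matrix(response)
  labels <- rownames(response)
  check_predictors(predictors, labels)
  n <- nrow(response)
  lt <- lower.tri(response)
  y <- response[lt]
  if (length(y) < length(predictors) + 2)
    stop("need at least 2 more pairs than predictors", call. = FALSE)
  X <- vapply(predictors, function(m) m[lt], numeric(length(y)))
  Xf <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xf)
  if (qrx$rank < ncol(Xf)) {
    drop <- colnames(Xf)[qrx$pivot[(qrx$rank + 1):ncol(Xf)]]
    stop("rank-deficient design; collinear predictor(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrx, y)
  res <- y - Xf %*% coefs
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / sst
  if (!is.null(seed)) set.seed(seed)
  cnt_coef <- numeric(length(predictors))
  cnt_r2 <- 0
  for (i in seq_len(permutations)) {
    idx <- sample.int(n)
    yp <- response[idx, idx][lt]
    cp <- qr.coef(qrx, yp)
    rp <- 1 - sum((yp - Xf %*% cp)^2) / sum((yp - mean(yp))^2)
    cnt_coef <- cnt_coef + (abs(cp[-1]) >= abs(coefs[-1]))
    cnt_r2 <- cnt_r2 + (rp >= r2)
  }
  pvals <- (cnt_coef + 1) / (permutations + 1)
  names(pvals) <- names(predictors)
  structure(list(coefficients = coefs, r2 = r2, pvals = pvals,
                 p_model = (cnt_r2 + 1) / (permutations + 1),
                 permutations = permutations, n_pairs = length(y)),
            class = "mrm_fit")
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat(sprintf("MRM fit: R2 = %.4f (p = %.3g, %d permutations, %d pairs)\n",
              x$r2, x$p_model, x$permutations, x$n_pairs))
  tab <- data.frame(coef = x$coefficients[-1], p = x$pvals)
  print(tab)
  invisible(x)
}

#' Forward selection of distance-matrix predictors
#'
#' Greedy forward selection for MRM: at each step the candidate giving
#' the largest R2 increase is evaluated; it enters if its permutation
#' p-value (on the partial coefficient) is below `alpha`, otherwise
#' selection stops. Ties in R2 gain are broken by candidate name order
#' for determinism. An empty selection is a valid result.
#'
#' @param response distance matrix
#' @param candidates named list of candidate distance matrices
#' @param alpha entry threshold on the permutation p (default 0.05)
#' @param permutations label permutations per test (default 999)
#' @param seed optional integer master seed (per-step seeds are derived)
#' @return list with `selected` (character vector, possibly empty),
#'   `fit` (final [mrm_fit()] over the selected set, or `NULL`) and
#'   `trace` (data.frame of evaluated steps)
#' @export
forward_select <- function(response, candidates, alpha = 0.05,
                           permutations = 999, seed = NULL) {
  assert_dist_matrix(response)
  check_predictors(candidates, rownames(response))
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  selected <- character(0)
  remaining <- sort(names(candidates))
  trace <- list()
  step <- 0L
  r2_cur <- 0
  repeat {
    if (!length(remaining)) break
    step <- step + 1L
    gains <- vapply(remaining, function(nm) {
      lt <- lower.tri(response)
      X <- vapply(candidates[c(selected, nm)], function(m) m[lt],
                  numeric(sum(lt)))
      ols_r2(response[lt], X) - r2_cur
    }, numeric(1))
    best <- remaining[which.max(gains)]  # which.max takes the first (name order) on ties
    fit_try <- mrm_fit(response, candidates[c(selected, best)],
                       permutations = permutations,
                       seed = (seed + step) %% 2147483647L)
    p_best <- fit_try$pvals[[best]]
    trace[[step]] <- data.frame(step = step, candidate = best,
                                r2_gain = gains[[best]], p = p_best,
                                entered = p_best < alpha)
    if (p_best >= alpha) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    r2_cur <- fit_try$r2
    final_fit <- fit_try
  }
  list(selected = selected,
       fit = if (length(selected)) final_fit else NULL,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(0), candidate = character(0),
                    r2_gain = numeric(0), p = numeric(0), entered = logical(0)))
}

#' Two-set variation partitioning of a pairwise response
#'
#' Partitions the MRM R2 of the response into pure spatial, pure
#' environmental, shared and unexplained fractions:
#' pure_space = R2_full - R2_env, pure_env = R2_full - R2_space,
#' shared = R2_space + R2_env - R2_full, unexplained = 1 - R2_full.
#' The shared fraction may be negative (a suppression effect) and is
#' reported as computed, never clipped.
#'
#' @param response distance matrix
#' @param space_set named list of spatial predictor matrices
#' @param env_set named list of environmental predictor matrices
#' @return object of class `vpa_result` with the four fractions plus
#'   `r2_full`, `r2_space`, `r2_env`
#' @export
vpa_two_sets <- function(response, space_set, env_set) {
  assert_dist_matrix(response)
  labels <- rownames(response)
  check_predictors(space_set, labels)
  check_predictors(env_set, labels)
  lt <- lower.tri(response)
  y <- response[lt]
  mat <- function(set) vapply(set, function(m) m[lt], numeric(length(y)))
  r2_full <- ols_r2(y, cbind(mat(space_set), mat(env_set)))
  r2_space <- ols_r2(y, mat(space_set))
  r2_env <- ols_r2(y, mat(env_set))
  structure(list(pure_space = r2_full - r2_env,
                 pure_env = r2_full - r2_space,
                 shared = r2_space + r2_env - r2_full,
                 unexplained = 1 - r2_full,
                 r2_full = r2_full, r2_space = r2_space, r2_env = r2_env),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat(sprintf("variation partitioning: pure space %.4f | pure env %.4f | shared %.4f | unexplained %.4f\n",
              x$pure_space, x$pure_env, x$shared, x$unexplained))
  invisible(x)
}

#' Hierarchical partitioning of predictor groups
#'
#' Independent contribution of each predictor group: the average, over
#' all orderings in which groups can enter the model, of the R2 increase
#' when the group enters. Computed exactly via the subset-average
#' formulation over all 2^(k-1) subsets not containing the group.
#' Contributions sum to the full-model R2.
#'
#' @param response distance matrix
#' @param groups named list (at most 5 entries) of named lists of
#'   distance matrices, e.g. `list(plant = ..., soil = ..., climate = ...,
#'   space = ...)`
#' @return object of class `hp_result`: `contributions` (named, summing
#'   to `r2_full`) and `r2_full`
#' @export
hierarchical_partition <- function(response, groups) {
  assert_dist_matrix(response)
  k <- length(groups)
  if (k < 1) stop("need at least one group", call. = FALSE)
  if (k > 5) stop("more than 5 groups: merge related predictors into groups", call. = FALSE)
  if (is.null(names(groups))) stop("`groups` must be named", call. = FALSE)
  labels <- rownames(response)
  for (g in groups) check_predictors(g, labels)
  lt <- lower.tri(response)
  y <- response[lt]
  gmats <- lapply(groups, function(set)
    vapply(set, function(m) m[lt], numeric(length(y))))
  # subsets indexed by bitmask: bit g set <=> group g in the model
  nmask <- bitwShiftL(1L, k)
  r2_of <- numeric(nmask)
  for (mask in seq_len(nmask - 1L)) {
    sel <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)))
    r2_of[mask + 1L] <- ols_r2(y, do.call(cbind, gmats[sel]))
  }
  contrib <- numeric(k)
  names(contrib) <- names(groups)
  for (g in seq_len(k)) {
    bit_g <- bitwShiftL(1L, g - 1L)
    for (mask in 0:(nmask - 1L)) {
      if (bitwAnd(mask, bit_g) != 0L) next
      s <- sum(as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L))))
      w <- factorial(s) * factorial(k - 1 - s) / factorial(k)
      contrib[g] <- contrib[g] +
        w * (r2_of[bitwOr(mask, bit_g) + 1L] - r2_of[mask + 1L])
    }
  }
  r2_full <- r2_of[nmask]
  structure(list(contributions = contrib, r2_full = unname(r2_full)),
            class = "hp_result")
}

#' @export
print.hp_result <- function(x, ...) {
  cat("hierarchical partitioning (independent contributions):\n")
  print(round(x$contributions, 4))
  cat(sprintf("full-model R2 = %.4f\n", x$r2_full))
  invisible(x)
}
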