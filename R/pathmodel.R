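#' Declare a recursive path model
#'
#' A directed acyclic graph over observed variables with exactly one
#' terminal outcome (a node with no outgoing edges). Endogenous variables
#' (those with parents) are each fit by OLS on their parents; effects on
#' the outcome are decomposed by path tracing.
#'
#' @param edges data.frame with columns `from`, `to` (one row per
#'   directed edge)
#' @return object of class `path_spec`: `edges`, `nodes`, `order`
#'   (topological), `outcome`
#' @export
path_spec <- function(edges) {
  if (!all(c("from", "to") %in% names(edges)))
    stop("`edges` needs columns from, to", call. = FALSE)
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to), stringsAsFactors = FALSE)
  nodes <- unique(c(edges$from, edges$to))
  # Kahn topological sort; leftover nodes mean a cycle
  order <- character(0)
  rem <- edges
  avail <- setdiff(nodes, rem$to)
  while (length(avail)) {
    order <- c(order, avail[1])
    rem <- rem[rem$from != avail[1], , drop = FALSE]
    avail <- setdiff(setdiff(nodes, order), rem$to)
  }
  if (length(order) != length(nodes))
    stop("path specification contains a cycle", call. = FALSE)
  terminal <- setdiff(nodes, edges$from)
  if (length(terminal) != 1L)
    stop("expected exactly one terminal outcome node, found: ",
         paste(terminal, collapse = ", "), call. = FALSE)
  structure(list(edges = edges, nodes = nodes, order = order,
                 outcome = terminal), class = "path_spec")
}

#' Fit a recursive path model
#'
#' All variables are standardized internally (mean 0, SD 1), so every
#' coefficient is a standardized path coefficient; a single-parent
#' child's coefficient equals the pairwise Pearson correlation. Each
#' endogenous variable is regressed on its parents by OLS. The direct
#' effect of a variable on the outcome is the coefficient of its direct
#' edge (0 if absent); its indirect effect is the sum over all directed
#' paths of length >= 2 of the product of coefficients along the path;
#' total = direct + indirect.
#'
#' @param spec a [path_spec()]
#' @param data named list or data.frame of numeric vectors covering every
#'   node in the spec (typically unfolded pairwise vectors when the
#'   outcome is a beta-deviation; note pair non-independence inflates the
#'   nominal OLS precision)
#' @return object of class `path_fit`: `coefficients` (edge data.frame
#'   with `coef` and analytic `p`), `effects` (per-variable direct /
#'   indirect / total on the outcome), `r2` (named, per endogenous
#'   variable), `r2_outcome`
#' @export
fit_path_model <- function(spec, data) {
  stopifnot(inherits(spec, "path_spec"))
  data <- as.data.frame(data)
  missing <- setdiff(spec$nodes, names(data))
  if (length(missing))
    stop("data missing variable(s): ", paste(missing, collapse = ", "), call. = FALSE)
  z <- as.data.frame(scale(data[spec$nodes]))
  if (any(!is.finite(as.matrix(z))))
    stop("constant or non-finite variable(s) cannot be standardized", call. = FALSE)
  edges <- spec$edges
  edges$coef <- NA_real_
  edges$p <- NA_real_
  r2 <- c()
  for (child in unique(edges$to)) {
    parents <- edges$from[edges$to == child]
    X <- as.matrix(z[parents])
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient parent set for '", child, "'", call. = FALSE)
    fit <- stats::lm(z[[child]] ~ X)
    sm <- summary(fit)
    edges$coef[edges$to == child] <- unname(stats::coef(fit)[-1])
    edges$p[edges$to == child] <- sm$coefficients[-1, 4]
    r2[child] <- sm$r.squared
  }
  # path tracing: sum over all directed paths to the outcome of the
  # product of edge coefficients
  paths_to_outcome <- function(node) {
    if (node == spec$outcome) return(list(numeric(0)))
    out <- list()
    rows <- which(edges$from == node)
    for (r in rows) {
      for (tail in paths_to_outcome(edges$to[r])) {
        out[[length(out) + 1L]] <- c(edges$coef[r], tail)
      }
    }
    out
  }
  vars <- setdiff(spec$nodes, spec$outcome)
  eff <- do.call(rbind, lapply(vars, function(v) {
    paths <- paths_to_outcome(v)
    lens <- vapply(paths, length, integer(1))
    direct <- sum(vapply(paths[lens == 1], prod, numeric(1)))
    indirect <- sum(vapply(paths[lens > 1], prod, numeric(1)))
    data.frame(variable = v, direct = direct, indirect = indirect,
               total = direct + indirect, stringsAsFactors = FALSE)
  }))
  structure(list(coefficients = edges, effects = eff, r2 = r2,
                 r2_outcome = unname(r2[spec$outcome])),
            class = "path_fit")
}

#' Variance in the outcome explained by a path model
#'
#' @param fit a [fit_path_model()] result
#' @return R2 of the outcome's structural equation
#' @export
variance_explained <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  fit$r2_outcome
}

#' @export
print.path_fit <- function(x, ...) {
  cat("recursive path model\n")
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("outcome R2 = %.4f\n", x$r2_outcome))
  invisible(x)
}

#' Default assembly path diagram
#'
#' The a-priori causal structure used by the analysis workflow: space
#' drives soil, climate and plant dissimilarities; those three plus
#' space's direct edge drive the fungal beta-deviation; for the rare
#' subcommunity the plant-composition beta-deviation (PBD) enters as an
#' additional parent of the fungal deviation.
#'
#' @param include_pbd add the plant-composition-deviation parent (used
#'   for the rare subcommunity)
#' @return a [path_spec()]
#' @export
default_path_spec <- function(include_pbd = FALSE) {
  e <- data.frame(
    from = c("space", "space", "space", "space", "soil", "climate", "plant"),
    to = c("soil", "climate", "plant", "fungal_deviation",
           "fungal_deviation", "fungal_deviation", "fungal_deviation"),
    stringsAsFactors = FALSE)
  if (include_pbd)
    e <- rbind(e, data.frame(from = "pbd", to = "fungal_deviation"))
  path_spec(e)
}

#' Export a path specification as DOT
#'
#' @param spec a [path_spec()]
#' @param fit optional [fit_path_model()] result; edge labels then carry
#'   coefficients
#' @return character scalar with a Graphviz DOT document
#' @export
path_to_dot <- function(spec, fit = NULL) {
  edges <- if (!is.null(fit)) fit$coefficients else spec$edges
  lab <- if (!is.null(fit))
    sprintf(" [label=\"%.2f\"]", edges$coef) else ""
  paste0("digraph path {\n",
         paste0("  ", edges$from, " -> ", edges$to, lab, ";", collapse = "\n"),
         "\n}\n")
}
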