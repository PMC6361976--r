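# Reportable structure from a confident edge set: connected-component
# subnetworks, signed-edge tallies, and pairwise expression correlations.

#' Extract subnetworks from a directed edge list
#'
#' Subnetworks are the maximal weakly connected components of the directed
#' confident-edge graph (direction-blind connectivity, matching how signed
#' regulatory maps are usually drawn); a strong-connectivity mode is
#' available behind `mode`.  Components with at least `min_size` genes are
#' returned, ordered by decreasing size then by lexicographically smallest
#' gene id, with ids assigned in that order — so reports are diffable.
#'
#' @param edges data.frame with columns `regulator` and `target` (extra
#'   columns such as `coefficient`/`sign` are carried into each subnetwork's
#'   edge list).
#' @param min_size minimum component size kept; the default 6 keeps
#'   components with more than 5 genes.
#' @param mode `"weak"` (default) or `"strong"` connectivity.
#' @return list of subnetworks, each a list with `id`, `genes` (sorted),
#'   `edges`, `size`.
#' @export
extract_subnetworks <- function(edges, min_size = 6,
                                mode = c("weak", "strong")) {
  mode <- match.arg(mode)
  if (is.null(edges) || nrow(edges) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    edges[, c("regulator", "target"), drop = FALSE], directed = TRUE)
  comp <- igraph::components(g, mode = mode)
  members <- split(names(comp$membership), comp$membership)
  members <- members[vapply(members, length, 1L) >= min_size]
  if (length(members) == 0) return(list())
  members <- lapply(members, sort)
  ord <- order(-vapply(members, length, 1L),
               vapply(members, `[`, "", 1))
  members <- members[ord]
  lapply(seq_along(members), function(i) {
    genes <- members[[i]]
    sub <- edges[edges$regulator %in% genes & edges$target %in% genes, ,
                 drop = FALSE]
    rownames(sub) <- NULL
    list(id = i, genes = genes, edges = sub, size = length(genes))
  })
}

#' Count positive and negative regulations
#'
#' @param edges data.frame with a `sign` column of `"+"` / `"-"` (or a
#'   `coefficient` column from which signs are derived).
#' @return list with `n_positive`, `n_negative`, `n_total`.
#' @export
summarize_edges <- function(edges) {
  if (nrow(edges) == 0) {
    return(list(n_positive = 0L, n_negative = 0L, n_total = 0L))
  }
  sgn <- if ("sign" %in% names(edges)) {
    edges$sign
  } else if ("coefficient" %in% names(edges)) {
    ifelse(edges$coefficient > 0, "+", "-")
  } else {
    stop("edges carry neither a sign nor a coefficient column")
  }
  if (any(is.na(sgn)) || !all(sgn %in% c("+", "-"))) {
    stop("every edge must carry a sign of '+' or '-'")
  }
  np <- sum(sgn == "+")
  list(n_positive = np, n_negative = length(sgn) - np,
       n_total = length(sgn))
}

#' Pairwise expression correlation for a gene subset
#'
#' Pearson correlation matrix across samples for the requested genes, the
#' standard subnetwork-validation display.
#'
#' @param expression an [expression_matrix()].
#' @param genes character vector of >= 2 gene ids.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(expression, genes) {
  if (length(genes) < 2) stop("need at least 2 genes")
  missing <- setdiff(genes, colnames(expression$Y))
  if (length(missing)) {
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  }
  Y <- expression$Y[, genes, drop = FALSE]
  if (nrow(Y) < 3) stop("need at least 3 samples")
  v <- apply(Y, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ", paste(genes[v == 0], collapse = ", "))
  }
  stats::cor(Y)
}
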