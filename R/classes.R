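#' Genotype matrix with marker map
#'
#' Container for segregant genotypes: an `n x q` numeric matrix of biallelic
#' calls coded 0/1 (possibly `NA` before imputation, or fractional after mean
#' imputation) together with a marker map giving each marker's chromosome,
#' genetic position (centiMorgans) and physical position (base pairs).
#'
#' @param X numeric matrix, samples in rows, markers in columns. Column names
#'   must match `map$marker_id`; row names are sample ids.
#' @param map data.frame with columns `marker_id`, `chrom`, `cm`
#'   (non-negative genetic position) and `bp` (positive physical position),
#'   one row per column of `X`, sorted by position within each chromosome.
#' @return An object of class `"genotype_matrix"`: a list with elements `X`
#'   and `map`.
#' @export
genotype_matrix <- function(X, map) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  req <- c("marker_id", "chrom", "cm", "bp")
  if (!all(req %in% names(map))) {
    stop("marker map must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(map$marker_id)) {
    stop("duplicate marker ids: ",
         paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  }
  if (ncol(X) != nrow(map)) {
    stop("genotype matrix has ", ncol(X), " columns but map has ",
         nrow(map), " markers")
  }
  if (is.null(colnames(X))) colnames(X) <- map$marker_id
  if (!identical(colnames(X), as.character(map$marker_id))) {
    stop("genotype column names do not match map$marker_id (same order required)")
  }
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  validate_marker_map(map)
  bad <- !(is.na(X) | X == 0 | X == 1 | (X > 0 & X < 1))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid genotype value ", X[bad][1], " at sample row ", idx[1],
         ", marker column ", idx[2], " (", colnames(X)[idx[2]], ")")
  }
  structure(list(X = X, map = map), class = "genotype_matrix")
}

validate_marker_map <- function(map) {
  for (ch in unique(map$chrom)) {
    cm <- map$cm[map$chrom == ch]
    bp <- map$bp[map$chrom == ch]
    if (is.unsorted(cm) || is.unsorted(bp)) {
      stop("marker map not sorted by position on chromosome ", ch)
    }
    if (any(cm < 0) || any(bp <= 0)) {
      stop("marker positions must be cm >= 0 and bp > 0 (chromosome ", ch, ")")
    }
  }
  invisible(map)
}

#' Expression matrix with gene annotation
#'
#' Container for an `n x p` numeric expression matrix (e.g. log2 ratios;
#' samples in rows) together with BED-like gene coordinates used to define
#' cis windows.
#'
#' @param Y numeric matrix, samples in rows, genes in columns; column names
#'   must match `genes$gene_id`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"` or `"-"`).
#' @return An object of class `"expression_matrix"`: a list with elements `Y`
#'   and `genes`.
#' @export
expression_matrix <- function(Y, genes) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("gene annotation must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (ncol(Y) != nrow(genes)) {
    stop("expression matrix has ", ncol(Y), " columns but annotation has ",
         nrow(genes), " genes")
  }
  if (is.null(colnames(Y))) colnames(Y) <- genes$gene_id
  if (!identical(colnames(Y), as.character(genes$gene_id))) {
    stop("expression column names do not match genes$gene_id (same order required)")
  }
  if (any(genes$start > genes$end)) stop("gene annotation has start > end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(rownames(Y))) rownames(Y) <- sprintf("S%03d", seq_len(nrow(Y)))
  structure(list(Y = Y, genes = genes), class = "expression_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$X), "samples x", ncol(x$X), "markers on",
      length(unique(x$map$chrom)), "chromosome(s);",
      sum(is.na(x$X)), "missing calls\n")
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$Y), "samples x", ncol(x$Y), "genes\n")
  invisible(x)
}

#' @export
print.network_estimate <- function(x, ...) {
  cat("network_estimate:", length(x$nodes), "node genes,",
      nrow(x$edges), "directed edges (",
      sum(x$edges$sign == "+"), "positive /",
      sum(x$edges$sign == "-"), "negative )\n")
  invisible(x)
}

# shared helper: n of aligned sample rows, with alignment check
check_sample_alignment <- function(expression, genotypes) {
  es <- rownames(expression$Y)
  gs <- rownames(genotypes$X)
  if (!identical(es, gs)) {
    off <- union(setdiff(es, gs), setdiff(gs, es))
    if (length(off) == 0) off <- es[es != gs]
    stop("expression and genotype sample rows are not aligned; offending ids: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  length(es)
}
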