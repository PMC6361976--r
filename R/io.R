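# On-disk formats: TSV matrices (samples in rows, NA literal "NA"), BED-like
# annotation tables with explicit headers, sparse triplet tables, SIF and
# GraphML edge exports.  All writers are deterministic so runs diff cleanly.

write_tsv <- function(df, path) {
  # %.17g guarantees doubles survive a write/read round trip bit-identically
  isd <- vapply(df, is.double, logical(1))
  df[isd] <- lapply(df[isd], function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- NA
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

matrix_to_df <- function(M) {
  data.frame(sample_id = rownames(M), M, check.names = FALSE,
             stringsAsFactors = FALSE)
}

df_to_matrix <- function(df, what) {
  if (names(df)[1] != "sample_id") {
    stop(what, " table must have a leading sample_id column")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", what)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- df$sample_id
  M
}

#' Write / read a genotype matrix and its marker map
#'
#' The genotype table is samples-in-rows TSV with a `sample_id` column and
#' one column per marker (`NA` for missing calls); the marker map is a
#' BED-like TSV (`chrom`, `start`, `end`, `id`, `strand`, `cm`) in 0-based
#' half-open coordinates, where `start` is the marker's physical position.
#'
#' @param genotypes a [genotype_matrix()].
#' @param geno_path,map_path file paths.
#' @return `write_genotypes` returns the paths invisibly; `read_genotypes`
#'   returns a validated [genotype_matrix()].
#' @export
write_genotypes <- function(genotypes, geno_path, map_path) {
  write_tsv(matrix_to_df(genotypes$X), geno_path)
  map <- genotypes$map
  write_tsv(data.frame(chrom = map$chrom, start = map$bp,
                       end = map$bp + 1L, id = map$marker_id, strand = ".",
                       cm = map$cm, stringsAsFactors = FALSE), map_path)
  invisible(c(geno_path, map_path))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(geno_path, map_path) {
  gdf <- read_tsv(geno_path)
  X <- df_to_matrix(gdf, "genotype")
  bad <- !is.na(X) & X != 0 & X != 1
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid genotype value ", X[idx[1], idx[2]], " at row ", idx[1],
         " (", rownames(X)[idx[1]], "), column ", idx[2], " (",
         colnames(X)[idx[2]], "): expected 0, 1 or NA")
  }
  mdf <- read_tsv(map_path)
  map <- data.frame(marker_id = mdf$id, chrom = mdf$chrom,
                    cm = as.numeric(mdf$cm), bp = mdf$start,
                    stringsAsFactors = FALSE)
  genotype_matrix(X, map)
}

#' Write / read an expression matrix and its gene annotation
#'
#' The expression table is samples-in-rows TSV with a `sample_id` column;
#' the annotation is BED-like TSV (`chrom`, `start`, `end`, `id`, `strand`),
#' 0-based half-open.
#'
#' @param expression an [expression_matrix()].
#' @param expr_path,annot_path file paths.
#' @return `write_expression` returns the paths invisibly;
#'   `read_expression` returns a validated [expression_matrix()].
#' @export
write_expression <- function(expression, expr_path, annot_path) {
  write_tsv(matrix_to_df(expression$Y), expr_path)
  g <- expression$genes
  write_tsv(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                       id = g$gene_id, strand = g$strand,
                       stringsAsFactors = FALSE), annot_path)
  invisible(c(expr_path, annot_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(expr_path, annot_path) {
  Y <- df_to_matrix(read_tsv(expr_path), "expression")
  a <- read_tsv(annot_path)
  genes <- data.frame(gene_id = a$id, chrom = a$chrom, start = a$start,
                      end = a$end, strand = a$strand,
                      stringsAsFactors = FALSE)
  expression_matrix(Y, genes)
}

#' Read an aligned expression + genotype dataset
#'
#' Reads the four tables and verifies the sample rows of the expression and
#' genotype matrices are identical and in the same order; a shuffled file is
#' rejected, never silently realigned.
#'
#' @param expr_path,annot_path,geno_path,map_path file paths.
#' @return list with `expression` and `genotypes`.
#' @export
read_dataset <- function(expr_path, annot_path, geno_path, map_path) {
  expression <- read_expression(expr_path, annot_path)
  genotypes <- read_genotypes(geno_path, map_path)
  check_sample_alignment(expression, genotypes)
  list(expression = expression, genotypes = genotypes)
}

#' Write a matrix as sparse triplets
#'
#' One row per nonzero entry: `row_id`, `col_id`, `value` — the format used
#' for ground-truth Gamma/Psi matrices in test harnesses.
#'
#' @param M matrix with dimnames.
#' @param path file path.
#' @export
write_triplets <- function(M, path) {
  nz <- which(M != 0, arr.ind = TRUE)
  rid <- rownames(M) %||% as.character(seq_len(nrow(M)))
  cid <- colnames(M) %||% as.character(seq_len(ncol(M)))
  df <- data.frame(row_id = rid[nz[, 1]], col_id = cid[nz[, 2]],
                   value = M[nz], stringsAsFactors = FALSE)
  df <- df[order(df$row_id, df$col_id), , drop = FALSE]
  write_tsv(df, path)
}

#' Read a sparse triplet table back into a dense matrix
#'
#' @param path file path written by [write_triplets()].
#' @param row_ids,col_ids full dimnames of the reconstructed matrix.
#' @return numeric matrix.
#' @export
read_triplets <- function(path, row_ids, col_ids) {
  df <- read_tsv(path)
  M <- matrix(0, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  M[cbind(match(df$row_id, row_ids), match(df$col_id, col_ids))] <- df$value
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an edge list as SIF and GraphML
#'
#' SIF rows are `regulator <sign> target`; GraphML is written through
#' igraph with the coefficient and sign as edge attributes.
#'
#' @param edges data.frame with `regulator`, `target` and optionally
#'   `coefficient` / `sign`.
#' @param path output path.
#' @export
write_sif <- function(edges, path) {
  sgn <- if ("sign" %in% names(edges)) edges$sign else rep("+", nrow(edges))
  lines <- paste(edges$regulator, sgn, edges$target, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
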