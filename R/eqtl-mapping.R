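# cis-eQTL mapping: mean imputation, strand-aware cis windows, per-marker
# simple linear regression, and the greedy correlation-pruned top-3 filter.

#' Mean-impute missing genotypes
#'
#' Replaces each missing call by the per-marker mean of the observed calls;
#' observed entries are untouched, so post-imputation column means equal the
#' observed-value means exactly.
#'
#' @param genotypes a [genotype_matrix()], possibly with `NA` entries.
#' @return A complete, real-valued [genotype_matrix()].
#' @export
impute_missing <- function(genotypes) {
  X <- genotypes$X
  if (!anyNA(X)) return(genotypes)
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0)) {
    stop("marker(s) with no observed genotype: ",
         paste(colnames(X)[n_obs == 0], collapse = ", "))
  }
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  genotype_matrix(X, genotypes$map)
}

#' Cis window of a gene
#'
#' The candidate-marker window: the gene body extended `upstream_bp` base
#' pairs upstream (before `start` on the + strand, after `end` on the -
#' strand), clamped at position 0.  Coordinates are 0-based half-open.  With
#' `strand_aware = FALSE` the upstream extension is applied before `start`
#' regardless of strand (a replication mode for strand-ignorant analyses).
#'
#' @param gene one-row data.frame (or list) with `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param upstream_bp non-negative upstream extension, default 500.
#' @param strand_aware honour the gene's strand?
#' @return list with `gene_id`, `chrom`, `start`, `end`.
#' @export
cis_window <- function(gene, upstream_bp = 500, strand_aware = TRUE) {
  if (!is.numeric(upstream_bp) || upstream_bp < 0) {
    stop("upstream_bp must be non-negative")
  }
  start <- gene$start
  end <- gene$end
  if (!strand_aware || gene$strand == "+") {
    start <- max(0, start - upstream_bp)
  } else {
    end <- end + upstream_bp
  }
  list(gene_id = gene$gene_id, chrom = gene$chrom,
       start = as.numeric(start), end = as.numeric(end))
}

#' Scan markers in a cis window by simple linear regression
#'
#' For each marker column `x`, fits `y = a + b x` by least squares and
#' reports the slope, the t statistic for `H0: b = 0`, and the two-sided
#' p-value from the t distribution with `n - 2` degrees of freedom.
#' Zero-variance markers are skipped with a warning.
#'
#' @param y numeric expression vector (length `n >= 3`).
#' @param X numeric genotype matrix of the window's markers (columns named).
#' @param bp optional marker physical positions (used downstream for
#'   deterministic tie-breaking); recycled into the result.
#' @return data.frame with columns `marker_id`, `bp`, `slope`, `t`, `p`.
#' @export
scan_cis_eqtl <- function(y, X, bp = NULL) {
  n <- length(y)
  if (n < 3) stop("need at least 3 samples for the cis scan")
  X <- as.matrix(X)
  if (nrow(X) != n) stop("y and X have different sample counts")
  if (is.null(bp)) bp <- rep(NA_real_, ncol(X))
  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  keep <- sxx > 0
  if (any(!keep)) {
    warning("skipping zero-variance marker(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  xc <- xc[, keep, drop = FALSE]
  sxx <- sxx[keep]
  sxy <- as.vector(crossprod(xc, yc))
  b <- sxy / sxx
  rss <- pmax(sum(yc^2) - b^2 * sxx, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- ifelse(se > 0, b / se, ifelse(b == 0, 0, sign(b) * Inf))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(marker_id = colnames(X)[keep], bp = bp[keep], slope = b,
             t = tstat, p = pval, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Greedy correlation-pruned selection of cis-eQTL
#'
#' Keeps markers with `p < alpha`, processes them in ascending-p order (ties
#' broken by genomic position, leftmost first), greedily retains a marker
#' only if its absolute genotype correlation with every already-retained
#' marker is below `corr_max`, and truncates to the first `max_k` retained —
#' the deterministic reading of "keep the strongest associations with
#' pairwise correlation controlled under 0.90".
#'
#' @param scan data.frame from [scan_cis_eqtl()].
#' @param genotypes imputed genotype columns for the scanned markers
#'   (matrix with column names matching `scan$marker_id`).
#' @param alpha per-marker significance level, default 0.05.
#' @param corr_max correlation bound, default 0.90.
#' @param max_k maximum markers kept, default 3.
#' @return the selected rows of `scan`, in selection order, with a `rank`
#'   column; zero rows if no marker is significant.
#' @export
select_cis_eqtl <- function(scan, genotypes, alpha = 0.05, corr_max = 0.90,
                            max_k = 3) {
  sig <- scan[scan$p < alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(cbind(scan[0, , drop = FALSE], rank = integer(0)))
  }
  ord <- order(sig$p, sig$bp)
  sig <- sig[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(sig))) {
    if (length(kept) >= max_k) break
    ok <- TRUE
    for (j in kept) {
      r <- stats::cor(genotypes[, sig$marker_id[i]],
                      genotypes[, sig$marker_id[j]])
      if (is.na(r) || abs(r) >= corr_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- sig[kept, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Map cis-eQTL for every gene
#'
#' Runs the whole mapping stage: mean imputation, per-gene cis-window scan,
#' and the greedy filtered selection.  Genes with an empty selection carry no
#' instrument and are excluded from the network node set.
#'
#' @param expression an [expression_matrix()].
#' @param genotypes a [genotype_matrix()] (missing calls allowed; imputed
#'   internally).
#' @param alpha,corr_max,max_k,upstream_bp,strand_aware stage parameters;
#'   defaults follow the standard segregant analysis (0.05, 0.90, 3, 500,
#'   strand-aware).
#' @return object of class `"cis_eqtl_map"`: list with `table` (data.frame
#'   gene_id, marker_id, slope, t, p, rank), `nodes` (gene ids with >= 1
#'   selected marker), `markers` (named list of selected marker ids per
#'   node gene), and `params`.
#' @export
map_cis_eqtl <- function(expression, genotypes, alpha = 0.05,
                         corr_max = 0.90, max_k = 3, upstream_bp = 500,
                         strand_aware = TRUE) {
  check_sample_alignment(expression, genotypes)
  imp <- impute_missing(genotypes)
  map <- imp$map
  rows <- vector("list", ncol(expression$Y))
  for (g in seq_len(ncol(expression$Y))) {
    gene <- expression$genes[g, ]
    win <- cis_window(gene, upstream_bp, strand_aware)
    in_win <- map$chrom == win$chrom & map$bp >= win$start & map$bp < win$end
    if (!any(in_win)) next
    Xw <- imp$X[, in_win, drop = FALSE]
    scan <- scan_cis_eqtl(expression$Y[, g], Xw, bp = map$bp[in_win])
    if (nrow(scan) == 0) next
    sel <- select_cis_eqtl(scan, Xw, alpha, corr_max, max_k)
    if (nrow(sel) == 0) next
    rows[[g]] <- data.frame(gene_id = gene$gene_id, sel,
                            stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(table)) {
    table <- data.frame(gene_id = character(0), marker_id = character(0),
                        bp = numeric(0), slope = numeric(0), t = numeric(0),
                        p = numeric(0), rank = integer(0))
  }
  nodes <- unique(table$gene_id)
  markers <- split(table$marker_id, factor(table$gene_id, levels = nodes))
  structure(list(table = table, nodes = nodes,
                 markers = as.list(markers),
                 params = list(alpha = alpha, corr_max = corr_max,
                               max_k = max_k, upstream_bp = upstream_bp,
                               strand_aware = strand_aware)),
            class = "cis_eqtl_map")
}

#' @export
print.cis_eqtl_map <- function(x, ...) {
  cat("cis_eqtl_map:", length(x$nodes), "genes with selected cis-eQTL,",
      nrow(x$table), "gene-marker pairs\n")
  invisible(x)
}
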