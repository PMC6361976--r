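# Bootstrap edge confidence: refit the network on datasets resampled with
# replacement, count how often each directed edge is selected, and bin the
# selection frequencies.

#' Bootstrap edge-selection frequencies
#'
#' Draws `B` bootstrap datasets by sampling the `n` segregants with
#' replacement (expression and genotype rows jointly), reruns the full
#' [fit_network()] pipeline on each with the SAME cis-eQTL map (the node set
#' is held fixed so edge frequencies stay well defined; set
#' `rescan_eqtl = TRUE` for a sensitivity mode that redoes the cis scan per
#' replicate), and tallies per-edge selection counts.  An edge counts as
#' identified in a replicate when its stage-2 coefficient is nonzero,
#' regardless of sign; sign agreement is reported separately.  Replicate
#' seeds are derived deterministically from the master seed, so the
#' frequency table is identical for any worker count.
#'
#' @param expression an [expression_matrix()].
#' @param genotypes a [genotype_matrix()] (rows aligned with expression).
#' @param cis_map a `cis_eqtl_map` from [map_cis_eqtl()].
#' @param B number of bootstrap replicates (>= 1).
#' @param seed master seed.
#' @param workers parallel workers (\code{parallel::mclapply}).
#' @param rescan_eqtl redo cis-eQTL selection inside each replicate?
#' @param ... further arguments passed to [fit_network()].
#' @return data.frame with columns `regulator`, `target`, `count`, `freq`
#'   (= count / B exactly), `modal_sign`, `sign_agreement`, plus attributes
#'   `B` and `seed`.
#' @export
bootstrap_network <- function(expression, genotypes, cis_map, B = 10000,
                              seed = 1, workers = 1L, rescan_eqtl = FALSE,
                              ...) {
  if (!is.numeric(B) || length(B) != 1 || B < 1) stop("B must be >= 1")
  B <- as.integer(B)
  n <- check_sample_alignment(expression, genotypes)
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, B)

  run_one <- function(b) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    expr_b <- expression
    expr_b$Y <- expression$Y[idx, , drop = FALSE]
    rownames(expr_b$Y) <- sprintf("B%06d", seq_len(n))
    geno_b <- genotypes
    geno_b$X <- genotypes$X[idx, , drop = FALSE]
    rownames(geno_b$X) <- rownames(expr_b$Y)
    cm <- if (rescan_eqtl) {
      do.call(map_cis_eqtl, c(list(expr_b, geno_b), cis_map$params))
    } else {
      cis_map
    }
    net <- tryCatch(fit_network(expr_b, geno_b, cm, ...),
                    error = function(e) NULL)
    if (is.null(net)) return(NULL)
    net$edges[, c("regulator", "target", "sign")]
  }

  reps <- if (workers > 1) {
    parallel::mclapply(seq_len(B), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(B), run_one)
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  all_edges <- do.call(rbind, reps)
  if (is.null(all_edges) || nrow(all_edges) == 0) {
    out <- data.frame(regulator = character(0), target = character(0),
                      count = integer(0), freq = numeric(0),
                      modal_sign = character(0),
                      sign_agreement = numeric(0))
  } else {
    key <- paste(all_edges$regulator, all_edges$target, sep = "\r")
    count <- table(key)
    pos <- tapply(all_edges$sign == "+", key, sum)
    ks <- names(count)
    cnt <- as.integer(count)
    npos <- as.integer(pos[ks])
    modal <- ifelse(npos * 2 >= cnt, "+", "-")
    agree <- pmax(npos, cnt - npos) / cnt
    parts <- strsplit(ks, "\r", fixed = TRUE)
    out <- data.frame(
      regulator = vapply(parts, `[`, "", 1),
      target = vapply(parts, `[`, "", 2),
      count = cnt, freq = cnt / B, modal_sign = modal,
      sign_agreement = agree, stringsAsFactors = FALSE
    )
    out <- out[order(-out$freq, out$regulator, out$target), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  out
}

#' Bin edges by bootstrap selection frequency
#'
#' Edges with frequency strictly above `threshold` are confident and fall in
#' the left-closed, right-open bins `[0.80, 0.90)`, `[0.90, 0.95)`,
#' `[0.95, 1.00)` or the singleton bin `1.00`; everything else is
#' `below_threshold`.
#'
#' @param freq_table data.frame from [bootstrap_network()] (needs `freq`),
#'   or a bare numeric vector of frequencies.
#' @param threshold confidence cut, default 0.80.
#' @return the input with added `bin` column (factor with levels
#'   `"[0.80,0.90)"`, `"[0.90,0.95)"`, `"[0.95,1.00)"`, `"1.00"`,
#'   `"below_threshold"`).
#' @export
confidence_bins <- function(freq_table, threshold = 0.80) {
  bare <- is.numeric(freq_table)
  freq <- if (bare) freq_table else freq_table$freq
  if (any(freq < 0 | freq > 1)) stop("frequencies must lie in [0, 1]")
  bin <- rep("below_threshold", length(freq))
  conf <- freq > threshold
  bin[conf & freq >= 0.80 & freq < 0.90] <- "[0.80,0.90)"
  bin[conf & freq >= 0.90 & freq < 0.95] <- "[0.90,0.95)"
  bin[conf & freq >= 0.95 & freq < 1] <- "[0.95,1.00)"
  bin[freq == 1] <- "1.00"
  bin <- factor(bin, levels = c("[0.80,0.90)", "[0.90,0.95)",
                                "[0.95,1.00)", "1.00", "below_threshold"))
  if (bare) {
    data.frame(freq = freq, bin = bin)
  } else {
    freq_table$bin <- bin
    freq_table
  }
}

#' Intersect confident edges with a point estimate
#'
#' Partitions the confident edge set into edges also present in the
#' original-data point estimate and bootstrap-only edges, and counts
#' positive/negative regulations using the point estimate's signs.
#'
#' @param confident_edges data.frame with `regulator` and `target` (e.g. the
#'   confident rows of [confidence_bins()] output).
#' @param point_network a `network_estimate` from [fit_network()].
#' @return list with `in_point` and `bootstrap_only` (edge data.frames),
#'   `n_positive`, `n_negative` (signs from the point estimate).
#' @export
intersect_with_point_estimate <- function(confident_edges, point_network) {
  pe <- point_network$edges
  ck <- paste(confident_edges$regulator, confident_edges$target, sep = "\r")
  pk <- paste(pe$regulator, pe$target, sep = "\r")
  hit <- ck %in% pk
  in_point <- confident_edges[hit, , drop = FALSE]
  signs <- pe$sign[match(ck[hit], pk)]
  in_point$point_sign <- signs
  list(in_point = in_point,
       bootstrap_only = confident_edges[!hit, , drop = FALSE],
       n_positive = sum(signs == "+"),
       n_negative = sum(signs == "-"))
}
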