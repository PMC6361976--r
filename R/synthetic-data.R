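# Synthetic segregant world: genotypes from a Markov chain along each
# chromosome (Haldane map function), expression from the structural-equation
# system Y = Y Gamma + X Psi + E with known ground truth.

#' Build a regular marker map
#'
#' Convenience constructor for an evenly spaced marker map, the synthetic
#' stand-in for a genotyping panel on a haploid cross.
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers per chromosome.
#' @param spacing_cm genetic distance between adjacent markers (centiMorgans).
#' @param spacing_bp physical distance between adjacent markers (base pairs).
#' @return data.frame with columns `marker_id`, `chrom`, `cm`, `bp`.
#' @export
sim_marker_map <- function(n_chr = 4, markers_per_chr = 30, spacing_cm = 5,
                           spacing_bp = 5000) {
  stopifnot(n_chr >= 1, markers_per_chr >= 1, spacing_cm >= 0, spacing_bp > 0)
  do.call(rbind, lapply(seq_len(n_chr), function(ch) {
    k <- seq_len(markers_per_chr)
    data.frame(
      marker_id = sprintf("chr%02d_m%03d", ch, k),
      chrom = sprintf("chr%02d", ch),
      cm = (k - 1) * spacing_cm,
      bp = 1 + (k - 1) * spacing_bp,
      stringsAsFactors = FALSE
    )
  }))
}

#' Simulate haploid segregant genotypes
#'
#' Each chromosome is a two-state Markov chain along its markers: the first
#' marker is Bernoulli(0.5) and the recombination fraction between adjacent
#' markers at genetic distance `d` Morgans follows Haldane's map function
#' `r = 0.5 * (1 - exp(-2 d))`.  Chromosomes segregate independently, as in a
#' single meiosis of a biparental haploid cross.
#'
#' @param n number of segregants (>= 2).
#' @param map marker map data.frame (see [sim_marker_map()]); must be sorted
#'   by position within each chromosome.
#' @param seed integer RNG seed.
#' @return A [genotype_matrix()] with entries in `{0, 1}`.
#' @export
simulate_segregant_genotypes <- function(n, map, seed) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("n must be a single integer >= 2")
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (nrow(map) < 1) stop("map must contain at least one marker")
  validate_marker_map(map)
  set.seed(seed)
  n <- as.integer(n)
  X <- matrix(NA_real_, n, nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    cm <- map$cm[idx]
    cur <- stats::rbinom(n, 1, 0.5)
    X[, idx[1]] <- cur
    if (length(idx) > 1) {
      r <- 0.5 * (1 - exp(-2 * diff(cm) / 100))
      for (k in seq_along(r)) {
        cur <- (cur + stats::rbinom(n, 1, r[k])) %% 2
        X[, idx[k + 1]] <- cur
      }
    }
  }
  colnames(X) <- map$marker_id
  rownames(X) <- sprintf("S%03d", seq_len(n))
  genotype_matrix(X, map)
}

#' Simulate a sparse ground-truth regulatory network
#'
#' Draws a `p x p` zero-diagonal matrix of regulatory effects Gamma, where
#' `Gamma[i, j] != 0` means gene `i` regulates gene `j`.  Each off-diagonal
#' entry is nonzero independently with probability `edges_per_gene / (p - 1)`
#' (so the expected out-degree is `edges_per_gene`); nonzero magnitudes are
#' uniform on `[effect_low, effect_high]` with random sign.  If
#' `acyclic = TRUE` edges run only from lower to higher gene index, so
#' `I - Gamma` is always invertible; otherwise draws are rejected and
#' resampled until the spectral radius of Gamma is below 1 (at most
#' `max_tries` attempts).
#'
#' @param p number of genes (>= 2).
#' @param edges_per_gene expected out-degree (non-negative real).
#' @param effect_low,effect_high bounds on absolute effect size,
#'   `0 < effect_low <= effect_high`.
#' @param acyclic restrict edges to lower -> higher index?
#' @param seed integer RNG seed.
#' @param max_tries resampling budget for the stability check.
#' @return `p x p` numeric matrix with zero diagonal.
#' @export
simulate_network <- function(p, edges_per_gene = 2, effect_low = 0.5,
                             effect_high = 1, acyclic = TRUE, seed,
                             max_tries = 100L) {
  if (!is.numeric(p) || length(p) != 1 || p < 2) stop("p must be >= 2")
  stopifnot(edges_per_gene >= 0, effect_low > 0, effect_low <= effect_high)
  set.seed(seed)
  p <- as.integer(p)
  # in acyclic mode only the p(p-1)/2 upper-triangular pairs are eligible,
  # so the per-pair probability is doubled to keep the average out-degree
  # at edges_per_gene
  prob <- min(1, edges_per_gene / (p - 1) * if (acyclic) 2 else 1)
  for (try in seq_len(max_tries)) {
    gamma <- matrix(0, p, p)
    present <- matrix(stats::runif(p * p) < prob, p, p)
    diag(present) <- FALSE
    if (acyclic) present[lower.tri(present, diag = TRUE)] <- FALSE
    k <- sum(present)
    if (k > 0) {
      gamma[present] <- stats::runif(k, effect_low, effect_high) *
        sample(c(-1, 1), k, replace = TRUE)
    }
    if (acyclic) return(gamma)  # strictly triangular: always stable
    rho <- max(Mod(eigen(gamma, only.values = TRUE)$values))
    if (is.finite(rho) && rho < 1) return(gamma)
  }
  stop("could not draw a stable network (spectral radius < 1) in ",
       max_tries, " attempts; reduce edges_per_gene or effect sizes")
}

#' Generate SEM-consistent expression
#'
#' Solves the structural-equation system `Y = Y Gamma + X Psi + E` for the
#' reduced form `Y = (X Psi + E) (I - Gamma)^{-1}` with
#' `E ~ iid Normal(0, noise_sd^2)`.  `Gamma[i, j] != 0` means gene `i`
#' regulates gene `j`; rows of `Y` are samples.
#'
#' @param genotypes a [genotype_matrix()] providing `X` (`n x q`).
#' @param truth a list with elements `gamma` (`p x p`, zero diagonal), `psi`
#'   (`q x p`, nonzero only at each gene's own cis markers), `noise_sd`
#'   (positive) and `seed` (integer); see [simulation_truth()].
#' @param genes optional gene annotation data.frame (gene_id, chrom, start,
#'   end, strand). When omitted, placeholder coordinates are generated.
#' @param gene_cis_assignment optional named list mapping gene ids to the
#'   marker ids allowed to carry nonzero `psi`; validated when supplied.
#' @return An [expression_matrix()].
#' @export
generate_expression <- function(genotypes, truth, genes = NULL,
                                gene_cis_assignment = NULL) {
  X <- genotypes$X
  gamma <- truth$gamma
  psi <- truth$psi
  p <- ncol(gamma)
  if (any(diag(gamma) != 0)) stop("gamma must have a zero diagonal")
  if (nrow(psi) != ncol(X)) stop("psi must have one row per marker")
  if (ncol(psi) != p) stop("psi must have one column per gene")
  if (any(colSums(psi != 0) > 3)) {
    stop("each gene may have at most 3 nonzero cis effects in psi")
  }
  gene_ids <- colnames(psi)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(p))
  if (!is.null(gene_cis_assignment)) {
    for (g in names(gene_cis_assignment)) {
      mk <- gene_cis_assignment[[g]]
      if (!all(mk %in% rownames(psi))) {
        stop("cis assignment for ", g, " references unknown markers")
      }
      nz <- rownames(psi)[psi[, match(g, gene_ids)] != 0]
      if (!all(nz %in% mk)) {
        stop("psi for ", g, " is nonzero outside its cis assignment")
      }
    }
  }
  ImG <- diag(p) - gamma
  if (!is.finite(rcond(ImG)) || rcond(ImG) < 1e-12) {
    stop("(I - Gamma) is singular or numerically singular; ",
         "cannot solve the structural-equation system")
  }
  set.seed(truth$seed)
  E <- matrix(stats::rnorm(nrow(X) * p, 0, truth$noise_sd), nrow(X), p)
  Y <- (X %*% psi + E) %*% solve(ImG)
  colnames(Y) <- gene_ids
  rownames(Y) <- rownames(X)
  if (is.null(genes)) {
    genes <- data.frame(gene_id = gene_ids, chrom = "chrU",
                        start = seq_len(p) * 10000L,
                        end = seq_len(p) * 10000L + 1000L,
                        strand = "+", stringsAsFactors = FALSE)
  }
  expression_matrix(Y, genes)
}

#' Bundle ground-truth simulation parameters
#'
#' @param gamma `p x p` regulatory-effect matrix, zero diagonal.
#' @param psi `q x p` cis-effect matrix (at most 3 nonzeros per column).
#' @param noise_sd positive error standard deviation.
#' @param seed integer seed used by [generate_expression()].
#' @return list of class `"simulation_truth"`.
#' @export
simulation_truth <- function(gamma, psi, noise_sd, seed) {
  stopifnot(is.matrix(gamma), nrow(gamma) == ncol(gamma),
            all(diag(gamma) == 0), is.matrix(psi), ncol(psi) == ncol(gamma),
            noise_sd > 0)
  if (any(colSums(psi != 0) > 3)) stop("psi has a gene with > 3 cis effects")
  ImG <- diag(ncol(gamma)) - gamma
  if (!is.finite(rcond(ImG)) || rcond(ImG) < 1e-12) {
    stop("(I - Gamma) must be invertible")
  }
  structure(list(gamma = gamma, psi = psi, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Knock out genotype calls at random
#'
#' Sets each genotype entry to `NA` independently with probability `rate`,
#' emulating the missing calls that are later mean-imputed.
#'
#' @param genotypes a [genotype_matrix()].
#' @param rate missing probability in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return A [genotype_matrix()] with the same marker map.
#' @export
inject_missing_genotypes <- function(genotypes, rate, seed) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must be in [0, 1)")
  }
  if (rate == 0) return(genotypes)
  set.seed(seed)
  X <- genotypes$X
  mask <- stats::runif(length(X)) < rate
  X[mask] <- NA_real_
  genotype_matrix(X, genotypes$map)
}

#' Simulate a complete segregant dataset with known truth
#'
#' One call builds the whole stated world: a marker map where each gene owns
#' a small block of 1-3 tightly linked cis markers (blocks separated by
#' `gene_gap_cm` so neighbouring genes' instruments decorrelate), segregant
#' genotypes, a sparse ground-truth network, cis effects, and
#' SEM-consistent expression.  Gene bodies span their own cis markers so the
#' 500 bp upstream cis window recovers exactly the intended instruments.
#'
#' Defaults emulate the shape of a classical yeast segregant cross scaled to
#' desk size: n = 112 haploid segregants, genes driven by 1-3 cis-eQTL of
#' absolute effect 0.8-1.2, sparse inter-gene regulation with absolute
#' effects 0.5-1, Gaussian noise.
#'
#' @param n samples (segregants).
#' @param p genes.
#' @param edges_per_gene expected true out-degree.
#' @param effect_range absolute range of regulatory effects.
#' @param cis_effect_range absolute range of cis effects.
#' @param cis_per_gene candidate numbers of cis markers per gene.
#' @param noise_sd error standard deviation.
#' @param n_chr chromosomes to spread genes over.
#' @param acyclic acyclic ground truth? (see [simulate_network()]).
#' @param marker_gap_cm genetic spacing of markers inside a gene's block.
#' @param gene_gap_cm genetic gap between consecutive gene blocks.
#' @param missing_rate genotype missingness injected after simulation.
#' @param seed master seed; all stage seeds are derived from it.
#' @return list with `genotypes`, `expression`, `truth`
#'   (a [simulation_truth()]), and `cis_assignment` (named list of marker ids
#'   per gene).
#' @export
sim_dataset <- function(n = 112, p = 30, edges_per_gene = 2,
                        effect_range = c(0.5, 1),
                        cis_effect_range = c(0.8, 1.2),
                        cis_per_gene = 1:3, noise_sd = 0.3, n_chr = 4,
                        acyclic = TRUE, marker_gap_cm = 5, gene_gap_cm = 30,
                        missing_rate = 0, seed = 1) {
  stopifnot(p >= 2, n >= 2)
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 5)
  k <- sample(cis_per_gene, p, replace = TRUE)
  gene_chr <- rep(seq_len(n_chr), length.out = p)
  gene_ids <- sprintf("G%03d", seq_len(p))

  map <- NULL
  genes <- NULL
  assignment <- vector("list", p)
  names(assignment) <- gene_ids
  for (ch in seq_len(n_chr)) {
    on_chr <- which(gene_chr == ch)
    cm_cur <- 0
    bp_cur <- 2000L  # leave room for the upstream window above position 0
    for (g in on_chr) {
      cm <- cm_cur + marker_gap_cm * (seq_len(k[g]) - 1)
      bp <- bp_cur + 1000L * (seq_len(k[g]) - 1L)
      ids <- sprintf("%s_%s_m%d", gene_ids[g], sprintf("chr%02d", ch),
                     seq_len(k[g]))
      map <- rbind(map, data.frame(marker_id = ids,
                                   chrom = sprintf("chr%02d", ch),
                                   cm = cm, bp = bp,
                                   stringsAsFactors = FALSE))
      strand <- if (g %% 2 == 0) "-" else "+"
      genes <- rbind(genes, data.frame(gene_id = gene_ids[g],
                                       chrom = sprintf("chr%02d", ch),
                                       start = min(bp) - 100L,
                                       end = max(bp) + 100L,
                                       strand = strand,
                                       stringsAsFactors = FALSE))
      assignment[[gene_ids[g]]] <- ids
      cm_cur <- max(cm) + gene_gap_cm
      bp_cur <- max(bp) + 10000L
    }
  }
  genes <- genes[order(match(genes$gene_id, gene_ids)), , drop = FALSE]
  rownames(genes) <- NULL

  genotypes <- simulate_segregant_genotypes(n, map, seed = seeds[1])
  gamma <- simulate_network(p, edges_per_gene, effect_range[1],
                            effect_range[2], acyclic = acyclic,
                            seed = seeds[2])
  set.seed(seeds[3])
  psi <- matrix(0, nrow(map), p,
                dimnames = list(map$marker_id, gene_ids))
  for (g in seq_len(p)) {
    sgn <- sample(c(-1, 1), 1)  # one orientation per gene's cis block
    psi[assignment[[g]], g] <-
      sgn * stats::runif(k[g], cis_effect_range[1], cis_effect_range[2])
  }
  truth <- simulation_truth(gamma, psi, noise_sd, seed = seeds[4])
  expression <- generate_expression(genotypes, truth, genes = genes,
                                    gene_cis_assignment = assignment)
  if (missing_rate > 0) {
    genotypes <- inject_missing_genotypes(genotypes, missing_rate,
                                          seed = seeds[5])
  }
  list(genotypes = genotypes, expression = expression, truth = truth,
       cis_assignment = assignment)
}

#' Edge recovery against a known truth
#'
#' Compares the directed support of an estimated network with the nonzero
#' pattern of a ground-truth Gamma and reports precision and recall.
#'
#' @param truth_gamma true `p x p` effect matrix (row regulates column).
#' @param estimate a `network_estimate` from [fit_network()], or an edge
#'   data.frame with `regulator` and `target` columns.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
edge_recovery <- function(truth_gamma, estimate) {
  ids <- colnames(truth_gamma)
  if (is.null(ids)) ids <- sprintf("G%03d", seq_len(ncol(truth_gamma)))
  nz <- which(truth_gamma != 0, arr.ind = TRUE)
  true_edges <- paste(ids[nz[, 1]], ids[nz[, 2]], sep = "->")
  edges <- if (is.data.frame(estimate)) estimate else estimate$edges
  est_edges <- if (nrow(edges)) {
    paste(edges$regulator, edges$target, sep = "->")
  } else character(0)
  tp <- sum(est_edges %in% true_edges)
  fp <- length(est_edges) - tp
  fn <- length(true_edges) - tp
  list(precision = if (length(est_edges)) tp / length(est_edges) else NA_real_,
       recall = if (length(true_edges)) tp / length(true_edges) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
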