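# Fixture builders shared across test files.

read_tsv_for_test <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# a dataset with no true regulation except one planted directed edge
planted_edge_dataset <- function(n = 300, coef = 1, noise_sd = 0.1, seed = 1,
                                 p = 3, from = 1, to = 2) {
  base <- sim_dataset(n = n, p = p, edges_per_gene = 0, noise_sd = noise_sd,
                      seed = seed)
  gamma <- base$truth$gamma
  gamma[from, to] <- coef
  truth <- simulation_truth(gamma, base$truth$psi, noise_sd,
                            seed = base$truth$seed)
  expression <- generate_expression(base$genotypes, truth,
                                    genes = base$expression$genes,
                                    gene_cis_assignment = base$cis_assignment)
  list(genotypes = base$genotypes, expression = expression, truth = truth,
       cis_assignment = base$cis_assignment)
}

# random scan table + genotype columns for exercising the greedy filter
random_filter_instance <- function(n = 60, m = 8) {
  X <- matrix(rbinom(n * m, 1, 0.5), n, m)
  # induce some high-correlation pairs by copying columns with light noise
  for (j in seq(2, m, by = 3)) {
    flip <- rbinom(n, 1, 0.03)
    X[, j] <- (X[, j - 1] + flip) %% 2
  }
  colnames(X) <- sprintf("m%02d", seq_len(m))
  keep <- apply(X, 2, var) > 0
  X <- X[, keep, drop = FALSE]
  scan <- data.frame(marker_id = colnames(X),
                     bp = sample(1000 * seq_len(ncol(X))),
                     p = 10^runif(ncol(X), -4, 0),
                     stringsAsFactors = FALSE)
  list(scan = scan, X = X)
}

# random signed edge list over a small gene universe
random_edge_list <- function(n_edges, n_genes = 12) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  pairs <- expand.grid(regulator = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  idx <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  out <- pairs[idx, ]
  out$coefficient <- rnorm(nrow(out))
  out$sign <- ifelse(out$coefficient > 0, "+", "-")
  rownames(out) <- NULL
  out
}
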