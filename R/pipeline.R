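# End-to-end orchestration: map-eqtl -> fit -> bootstrap -> subnetworks,
# with one declarative config, one master seed, and a JSON manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the standard
#' segregant analysis: per-marker significance 0.05, pairwise-correlation
#' bound 0.90, at most 3 cis-eQTL per gene, a 500 bp upstream window,
#' 10,000 bootstrap replicates, an 80% confidence threshold, and a
#' more-than-5-genes subnetwork cutoff.  Invalid values are rejected here,
#' before any compute.
#'
#' @param expr_path,annot_path,geno_path,map_path input table paths (may be
#'   `NULL` when the pipeline is run on in-memory objects).
#' @param out_dir output directory.
#' @param alpha,corr_max,max_k,upstream_bp,strand_aware cis-eQTL stage.
#' @param ridge_grid,gamma,nlambda,lambda_min_ratio,penalize_cis,instrument_set
#'   network stage.
#' @param B,threshold bootstrap stage.
#' @param min_size subnetwork stage.
#' @param seed master seed (drives every source of randomness).
#' @param workers parallel workers.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(expr_path = NULL, annot_path = NULL, geno_path = NULL,
                       map_path = NULL, out_dir = NULL, alpha = 0.05,
                       corr_max = 0.90, max_k = 3, upstream_bp = 500,
                       strand_aware = TRUE,
                       ridge_grid = default_ridge_grid(), gamma = 1,
                       nlambda = 50, lambda_min_ratio = 1e-4,
                       penalize_cis = FALSE, instrument_set = "selected",
                       B = 10000, threshold = 0.80, min_size = 6, seed = 1,
                       workers = 1L) {
  stopifnot(alpha > 0, alpha < 1, corr_max > 0, corr_max <= 1, max_k >= 1,
            upstream_bp >= 0, gamma > 0, nlambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            threshold >= 0, threshold < 1, min_size >= 1, workers >= 1)
  if (!is.numeric(B) || length(B) != 1 || B < 1) {
    stop("B must be a positive integer (got ", B, ")")
  }
  structure(list(expr_path = expr_path, annot_path = annot_path,
                 geno_path = geno_path, map_path = map_path,
                 out_dir = out_dir, alpha = alpha, corr_max = corr_max,
                 max_k = max_k, upstream_bp = upstream_bp,
                 strand_aware = strand_aware, ridge_grid = ridge_grid,
                 gamma = gamma, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 penalize_cis = penalize_cis,
                 instrument_set = instrument_set, B = as.integer(B),
                 threshold = threshold, min_size = min_size,
                 seed = as.integer(seed), workers = as.integer(workers)),
            class = "run_config")
}

#' Run the full inference pipeline
#'
#' Executes cis-eQTL mapping, the two-stage network fit, the bootstrap
#' confidence assessment, the intersection with the point estimate, and
#' subnetwork extraction; optionally writes every result table plus a JSON
#' manifest to `config$out_dir`.  Outputs are byte-for-byte reproducible
#' from (inputs, config, seed): the manifest records parameters, seed,
#' package version and per-stage counts, never timestamps.
#'
#' @param config a [run_config()].
#' @param expression,genotypes optional in-memory inputs; when `NULL` they
#'   are read from the config paths.
#' @return list with `cis_map`, `network`, `boot` (binned frequency table),
#'   `confident` (rows above threshold), `intersection`, `subnetworks`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, expression = NULL, genotypes = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(expression) || is.null(genotypes)) {
    ds <- read_dataset(config$expr_path, config$annot_path,
                       config$geno_path, config$map_path)
    expression <- ds$expression
    genotypes <- ds$genotypes
  }
  cis_map <- map_cis_eqtl(expression, genotypes, alpha = config$alpha,
                          corr_max = config$corr_max, max_k = config$max_k,
                          upstream_bp = config$upstream_bp,
                          strand_aware = config$strand_aware)
  network <- fit_network(expression, genotypes, cis_map,
                         ridge_grid = config$ridge_grid,
                         gamma = config$gamma, nlambda = config$nlambda,
                         lambda_min_ratio = config$lambda_min_ratio,
                         penalize_cis = config$penalize_cis,
                         instrument_set = config$instrument_set,
                         workers = config$workers)
  boot <- bootstrap_network(expression, genotypes, cis_map, B = config$B,
                            seed = config$seed, workers = config$workers,
                            ridge_grid = config$ridge_grid,
                            gamma = config$gamma, nlambda = config$nlambda,
                            lambda_min_ratio = config$lambda_min_ratio,
                            penalize_cis = config$penalize_cis,
                            instrument_set = config$instrument_set)
  boot <- confidence_bins(boot, config$threshold)
  confident <- boot[boot$bin != "below_threshold", , drop = FALSE]
  intersection <- intersect_with_point_estimate(confident, network)
  subnets <- extract_subnetworks(confident, min_size = config$min_size)

  manifest <- list(
    package = "twospls",
    version = as.character(utils::packageVersion("twospls")),
    seed = config$seed,
    parameters = config[c("alpha", "corr_max", "max_k", "upstream_bp",
                          "strand_aware", "gamma", "nlambda",
                          "lambda_min_ratio", "penalize_cis",
                          "instrument_set", "B", "threshold", "min_size",
                          "workers")],
    counts = list(
      samples = nrow(expression$Y),
      genes = ncol(expression$Y),
      markers = ncol(genotypes$X),
      node_genes = length(cis_map$nodes),
      cis_pairs = nrow(cis_map$table),
      point_edges = nrow(network$edges),
      point_positive = sum(network$edges$sign == "+"),
      point_negative = sum(network$edges$sign == "-"),
      candidate_edges = nrow(boot),
      confident_edges = nrow(confident),
      confident_in_point = nrow(intersection$in_point),
      bin_counts = as.list(table(boot$bin)),
      subnetworks = length(subnets),
      subnetwork_sizes = vapply(subnets, `[[`, 1L, "size")
    )
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$out_dir, f)
    write_tsv(cis_map$table, o("cis_eqtl.tsv"))
    write_tsv(network$edges, o("edges.tsv"))
    write_triplets(network$psi_hat, o("psi_hat.tsv"))
    write_sif(network$edges, o("network.sif"))
    write_graphml(network$edges, o("network.graphml"))
    write_tsv(boot, o("edge_confidence.tsv"))
    membership <- if (length(subnets)) {
      do.call(rbind, lapply(subnets, function(s) {
        data.frame(subnetwork_id = s$id, gene_id = s$genes,
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(subnetwork_id = integer(0), gene_id = character(0))
    }
    write_tsv(membership, o("subnetworks.tsv"))
    for (s in subnets) {
      write_sif(s$edges, o(sprintf("subnetwork_%02d.sif", s$id)))
      write_graphml(s$edges, o(sprintf("subnetwork_%02d.graphml", s$id)))
    }
    jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  invisible(list(cis_map = cis_map, network = network, boot = boot,
                 confident = confident, intersection = intersection,
                 subnetworks = subnets, manifest = manifest))
}
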