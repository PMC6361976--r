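# Two-stage penalized least squares for the structural-equation system
# Y = Y Gamma + X Psi + E.  Stage 1 replaces each endogenous regressor by
# its ridge-predicted conditional expectation given the cis instruments;
# stage 2 selects each gene's regulators by adaptive lasso with the gene's
# own cis effects left unpenalized.

#' Stage-2 fit for one target gene
#'
#' Regresses the target's expression on the stage-1 fitted expectations of
#' all other node genes plus the target's own selected cis genotypes.  The
#' adaptive-lasso penalty applies to the regulator coefficients only, with
#' weights `w_j = 1 / |beta_pilot_j|^gamma` from a ridge pilot fit of the
#' same regression (a pilot coefficient of exactly 0 gets a large finite
#' weight cap, forcing the effect out).  The penalty level is chosen by BIC
#' over a descending log-spaced grid with warm starts; ties prefer the
#' sparser (larger-lambda) model.  All variables are mean-centered for the
#' fit and coefficients are reported on the original scale.
#'
#' @param y target gene expression vector.
#' @param y_hat_others `n x (p-1)` matrix of stage-1 fitted expectations of
#'   the other node genes (columns named by gene id); must exclude the
#'   target itself.
#' @param own_cis `n x k` genotype matrix of the target's selected cis-eQTL
#'   (columns named by marker id); may have 0 columns.
#' @param gamma adaptive-weight exponent, default 1.
#' @param nlambda,lambda_min_ratio penalty-grid shape.
#' @param ridge_grid pilot ridge grid, default [default_ridge_grid()].
#' @param weight_cap finite cap replacing infinite weights, default 1e12.
#' @param penalize_cis also penalize the cis coefficients? Default `FALSE`
#'   so every node retains its instrument (identifiability).
#' @return list with `gamma_coef` (named regulator coefficients),
#'   `psi_coef` (named cis coefficients), `lambda`, `bic`, `kkt`.
#' @export
stage2_fit_gene <- function(y, y_hat_others, own_cis, gamma = 1,
                            nlambda = 50, lambda_min_ratio = 1e-4,
                            ridge_grid = default_ridge_grid(),
                            weight_cap = 1e12, penalize_cis = FALSE) {
  y_hat_others <- as.matrix(y_hat_others)
  own_cis <- if (is.null(own_cis)) {
    matrix(0, length(y), 0)
  } else {
    as.matrix(own_cis)
  }
  p_reg <- ncol(y_hat_others)
  k_cis <- ncol(own_cis)
  D <- cbind(y_hat_others, own_cis)
  n <- length(y)
  yc <- y - mean(y)
  Dc <- if (ncol(D)) sweep(D, 2, colMeans(D)) else D
  reg_idx <- seq_len(p_reg)
  cis_idx <- if (k_cis) p_reg + seq_len(k_cis) else integer(0)
  unpen <- if (penalize_cis) integer(0) else cis_idx

  if (ncol(Dc) == 0 || all(colSums(Dc^2) == 0)) {
    # degenerate design: nothing to regress on
    return(list(gamma_coef = stats::setNames(rep(0, p_reg),
                                             colnames(y_hat_others)),
                psi_coef = stats::setNames(rep(0, k_cis), colnames(own_cis)),
                lambda = 0, bic = NA_real_, kkt = 0))
  }

  # pilot ridge fit of the same stage-2 regression -> adaptive weights
  pilot <- ridge_fit(Dc, yc, ridge_grid)
  w <- rep(0, ncol(Dc))
  pen_idx <- setdiff(seq_len(ncol(Dc)), unpen)
  pw <- 1 / abs(pilot$coef[pen_idx])^gamma
  pw[!is.finite(pw) | pw > weight_cap] <- weight_cap
  w[pen_idx] <- pw

  # lambda grid anchored at the null-penalized solution: residual after an
  # OLS fit on the unpenalized columns alone
  r0 <- yc
  if (length(unpen)) {
    Du <- Dc[, unpen, drop = FALSE]
    keep <- colSums(Du^2) > 0
    if (any(keep)) {
      fit0 <- stats::lm.fit(Du[, keep, drop = FALSE], yc)
      r0 <- fit0$residuals
    }
  }
  cvec0 <- as.vector(crossprod(Dc, r0)) / n
  grid <- lasso_lambda_grid(cvec0, w, pen_idx, nlambda, lambda_min_ratio)

  best <- NULL
  beta <- numeric(ncol(Dc))
  since_best <- 0L
  for (lam in grid) {
    sol <- adaptive_lasso(Dc, yc, w, lam, unpenalized = unpen,
                          beta_init = beta)
    beta <- sol$beta
    rss <- max(sum((yc - Dc %*% beta)^2), 1e-12)
    df <- sum(beta != 0)
    bic <- n * log(rss / n) + log(n) * df
    if (is.null(best) || bic < best$bic - 1e-12) {
      best <- list(beta = beta, lambda = lam, bic = bic, kkt = sol$kkt)
      since_best <- 0L
    } else {
      # BIC is past its minimum; the dense small-lambda tail is both
      # expensive and never selected, so stop after 10 stale points
      since_best <- since_best + 1L
      if (since_best >= 10L) break
    }
  }
  gamma_coef <- stats::setNames(best$beta[reg_idx], colnames(y_hat_others))
  psi_coef <- stats::setNames(if (k_cis) best$beta[cis_idx] else numeric(0),
                              colnames(own_cis))
  list(gamma_coef = gamma_coef, psi_coef = psi_coef, lambda = best$lambda,
       bic = best$bic, kkt = best$kkt)
}

#' Fit the gene regulatory network by two-stage penalized least squares
#'
#' The node set is the genes with at least one selected cis-eQTL.  Stage 1
#' ridge-predicts every node gene's conditional expectation from the common
#' instrument matrix (by default the union of all genes' selected cis
#' markers, optionally all markers); stage 2 then fits each node gene
#' independently — the fits share no state, so results are identical for any
#' worker count.
#'
#' @param expression an [expression_matrix()].
#' @param genotypes a [genotype_matrix()]; missing calls are mean-imputed.
#' @param cis_map a `cis_eqtl_map` from [map_cis_eqtl()].
#' @param ridge_grid stage-1/pilot ridge penalty grid.
#' @param gamma adaptive-weight exponent, default 1.
#' @param nlambda,lambda_min_ratio stage-2 penalty-grid shape.
#' @param penalize_cis passed to [stage2_fit_gene()].
#' @param instrument_set `"selected"` (union of selected cis markers) or
#'   `"all"` (every marker).
#' @param workers parallel workers for the per-gene stage-2 fits (forked via
#'   \code{parallel::mclapply}; results are worker-count invariant).
#' @return object of class `"network_estimate"`: list with `gamma_hat`
#'   (`p_nodes x p_nodes`, zero diagonal; entry (i, j) = effect of gene i on
#'   gene j), `psi_hat` (instrument x node matrix), `edges` (data.frame
#'   regulator, target, coefficient, sign), `nodes`, `stage1` (lambdas).
#' @export
fit_network <- function(expression, genotypes, cis_map,
                        ridge_grid = default_ridge_grid(), gamma = 1,
                        nlambda = 50, lambda_min_ratio = 1e-4,
                        penalize_cis = FALSE,
                        instrument_set = c("selected", "all"),
                        workers = 1L) {
  instrument_set <- match.arg(instrument_set)
  check_sample_alignment(expression, genotypes)
  nodes <- intersect(colnames(expression$Y), cis_map$nodes)
  if (length(nodes) < 2) {
    stop("need at least 2 node genes with selected cis-eQTL; got ",
         length(nodes))
  }
  imp <- impute_missing(genotypes)
  inst_markers <- if (instrument_set == "all") {
    colnames(imp$X)
  } else {
    unique(unlist(cis_map$markers[nodes], use.names = FALSE))
  }
  Xinst <- imp$X[, inst_markers, drop = FALSE]
  Y <- expression$Y[, nodes, drop = FALSE]
  n <- nrow(Y)

  # stage 1: one SVD of the centered instrument matrix serves every gene
  x_center <- colMeans(Xinst)
  sv <- svd(sweep(Xinst, 2, x_center))
  stage1 <- lapply(seq_along(nodes), function(j) {
    ridge_fit(NULL, Y[, j], ridge_grid, sv = sv, x_center = x_center)
  })
  y_hat <- vapply(stage1, `[[`, numeric(n), "fitted")
  colnames(y_hat) <- nodes

  fit_one <- function(j) {
    own <- cis_map$markers[[nodes[j]]]
    stage2_fit_gene(Y[, j], y_hat[, -j, drop = FALSE],
                    imp$X[, own, drop = FALSE], gamma = gamma,
                    nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                    ridge_grid = ridge_grid, penalize_cis = penalize_cis)
  }
  fits <- if (workers > 1) {
    parallel::mclapply(seq_along(nodes), fit_one, mc.cores = workers)
  } else {
    lapply(seq_along(nodes), fit_one)
  }

  p <- length(nodes)
  gamma_hat <- matrix(0, p, p, dimnames = list(nodes, nodes))
  psi_hat <- matrix(0, length(inst_markers), p,
                    dimnames = list(inst_markers, nodes))
  for (j in seq_len(p)) {
    gc <- fits[[j]]$gamma_coef
    gamma_hat[names(gc), j] <- gc
    pc <- fits[[j]]$psi_coef
    if (length(pc)) psi_hat[names(pc), j] <- pc
  }
  diag(gamma_hat) <- 0
  nz <- which(gamma_hat != 0, arr.ind = TRUE)
  edges <- data.frame(
    regulator = nodes[nz[, 1]], target = nodes[nz[, 2]],
    coefficient = gamma_hat[nz],
    sign = ifelse(gamma_hat[nz] > 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(gamma_hat = gamma_hat, psi_hat = psi_hat, edges = edges,
                 nodes = nodes,
                 stage1 = list(lambda = vapply(stage1, `[[`, numeric(1),
                                               "lambda")),
                 params = list(gamma = gamma, nlambda = nlambda,
                               lambda_min_ratio = lambda_min_ratio,
                               penalize_cis = penalize_cis,
                               instrument_set = instrument_set)),
            class = "network_estimate")
}
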