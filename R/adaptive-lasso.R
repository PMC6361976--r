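# Weighted-lasso solver: cyclic coordinate descent on
#   (1/2n) ||y - D beta||^2 + lambda * sum_j w_j |beta_j|
# with exact per-coordinate minimization, so the KKT conditions hold at
# convergence to machine precision.  This is the stage-2 selection engine.

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Weighted (adaptive) lasso by cyclic coordinate descent
#'
#' Minimizes `(1/2n) ||y - D beta||^2 + lambda * sum_j w_j |beta_j|`.
#' Columns listed in `unpenalized` have their weight forced to zero.  The
#' design is used as given (no internal centering or scaling); callers
#' handle the intercept by centering.
#'
#' @param D numeric `n x d` design matrix.
#' @param y numeric response vector.
#' @param weights `d` non-negative finite penalty weights.
#' @param lambda non-negative penalty level.
#' @param unpenalized integer indices of unpenalized columns.
#' @param beta_init optional warm start.
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep, default 1e-8.
#' @param max_sweeps sweep budget, default 10000; non-convergence is an
#'   error carrying the KKT residual.
#' @return list with `beta`, `kkt` (the KKT residual, see
#'   [lasso_kkt_residual()]), `sweeps`.
#' @export
adaptive_lasso <- function(D, y, weights, lambda, unpenalized = integer(0),
                           beta_init = NULL, tol = 1e-8,
                           max_sweeps = 10000L) {
  D <- as.matrix(D)
  d <- ncol(D)
  n <- nrow(D)
  if (length(y) != n) stop("y and D have different sample counts")
  if (length(weights) != d) stop("need one weight per column")
  if (any(!is.finite(D)) || any(!is.finite(y)) ||
      any(!is.finite(weights)) || !is.finite(lambda)) {
    stop("non-finite inputs to adaptive_lasso")
  }
  if (any(weights < 0) || lambda < 0) stop("weights and lambda must be >= 0")
  w <- weights
  w[unpenalized] <- 0
  G <- crossprod(D) / n
  cvec <- as.vector(crossprod(D, y)) / n
  gjj <- diag(G)
  beta <- if (is.null(beta_init)) numeric(d) else beta_init
  if (length(beta) != d) stop("beta_init has wrong length")
  usable <- which(gjj > 0)  # zero-variance columns stay at 0
  sweeps <- 0L
  if (d > 0 && length(usable) > 0) {
    Gbeta <- as.vector(G %*% beta)
    lw <- lambda * w
    one_sweep <- function(idx) {
      delta_max <- 0
      for (j in idx) {
        rj <- cvec[j] - Gbeta[j] + gjj[j] * beta[j]
        az <- abs(rj) - lw[j]  # scalar soft threshold, hot path
        bnew <- if (az > 0) sign(rj) * az / gjj[j] else 0
        db <- bnew - beta[j]
        if (db != 0) {
          Gbeta <<- Gbeta + G[, j] * db
          beta[j] <<- bnew
          if (abs(db) > delta_max) delta_max <- abs(db)
        }
      }
      delta_max
    }
    # glmnet-style active-set cycling: converge on the current support,
    # then one full sweep to admit new coordinates; stop when a full
    # sweep moves nothing
    repeat {
      sweeps <- sweeps + 1L
      if (one_sweep(usable) < tol || sweeps >= max_sweeps) break
      repeat {
        act <- usable[beta[usable] != 0]
        if (length(act) == 0) break
        sweeps <- sweeps + 1L
        if (one_sweep(act) < tol || sweeps >= max_sweeps) break
      }
      if (sweeps >= max_sweeps) break
    }
  }
  kkt <- lasso_kkt_residual(D, y, beta, weights, lambda, unpenalized)
  if (sweeps >= max_sweeps && kkt > 1e-6) {
    stop("adaptive_lasso did not converge in ", max_sweeps,
         " sweeps; KKT residual = ", format(kkt))
  }
  list(beta = beta, kkt = kkt, sweeps = sweeps)
}

#' KKT residual of a weighted-lasso solution
#'
#' For the objective `(1/2n) ||y - D beta||^2 + lambda sum_j w_j |beta_j|`,
#' the stationarity conditions are `|g_j| <= lambda w_j` for `beta_j = 0`
#' and `g_j = lambda w_j sign(beta_j)` otherwise, where
#' `g_j = (1/n) D_j' (y - D beta)`.  Returns the largest violation (0 at an
#' exact solution).
#'
#' @inheritParams adaptive_lasso
#' @param beta candidate coefficient vector.
#' @return non-negative scalar.
#' @export
lasso_kkt_residual <- function(D, y, beta, weights, lambda,
                               unpenalized = integer(0)) {
  w <- weights
  w[unpenalized] <- 0
  g <- as.vector(crossprod(D, y - D %*% beta)) / nrow(D)
  zero_var <- colSums(as.matrix(D)^2) == 0
  viol <- ifelse(beta == 0, pmax(abs(g) - lambda * w, 0),
                 abs(g - lambda * w * sign(beta)))
  viol[zero_var] <- 0
  if (length(viol) == 0) 0 else max(viol)
}

# Descending lambda grid for a weighted lasso: starts just above the level
# that zeroes every penalized coefficient in the null model.
lasso_lambda_grid <- function(cvec, w, penalized, nlambda = 50,
                              lambda_min_ratio = 1e-4) {
  pen <- penalized[w[penalized] > 0]
  if (length(pen) == 0) return(0)
  lmax <- max(abs(cvec[pen]) / w[pen])
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-4
  exp(seq(log(lmax * 1.001), log(lmax * lambda_min_ratio),
          length.out = nlambda))
}
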