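# Ridge regression with generalized cross-validation, used for the stage-1
# conditional-expectation fits and for the stage-2 adaptive-weight pilot.

#' Default ridge penalty grid
#'
#' 25 log-spaced points on 10^-4 .. 10^4, the deterministic grid searched by
#' generalized cross-validation.
#' @return numeric vector.
#' @export
default_ridge_grid <- function() 10^seq(-4, 4, length.out = 25)

# Core ridge solver on centered data via one SVD, shared across lambdas.
# Returns coefficients on the original scale plus GCV per lambda.
ridge_fit <- function(X, y, lambda_grid = default_ridge_grid(), sv = NULL,
                      x_center = NULL) {
  n <- length(y)
  if (is.null(sv)) {
    x_center <- colMeans(X)
    Xc <- sweep(X, 2, x_center)
    sv <- svd(Xc)
  }
  y_center <- mean(y)
  yc <- y - y_center
  d2 <- sv$d^2
  uty <- as.vector(crossprod(sv$u, yc))
  syy <- sum(yc^2)
  best <- NULL
  for (lam in lambda_grid) {
    shrink <- d2 / (d2 + lam)
    # RSS via Pythagoras in the U basis: fitted energy sum((shrink*uty)^2)
    rss <- syy - 2 * sum(shrink * uty^2) + sum((shrink * uty)^2)
    df <- sum(shrink)
    gcv <- n * rss / (n - df)^2
    if (is.null(best) || gcv < best$gcv) {
      best <- list(lambda = lam, gcv = gcv, shrink = shrink)
    }
  }
  coef_v <- sv$v %*% (sv$d / (d2 + best$lambda) * uty)
  fitted <- y_center + as.vector(sv$u %*% (best$shrink * uty))
  list(coef = as.vector(coef_v), intercept = y_center, lambda = best$lambda,
       fitted = fitted, gcv = best$gcv, x_center = x_center)
}

#' Stage-1 ridge prediction of a gene's conditional expectation
#'
#' Regresses one gene's expression on the instrument matrix (the union of
#' all selected cis markers) with a ridge penalty; the intercept is
#' unpenalized (fit on mean-centered data, mean added back) and the penalty
#' is chosen from `lambda_grid` by generalized cross-validation.  The fitted
#' vector estimates `E[y | X]`, the surrogate used in place of the raw
#' (endogenous) expression in stage 2.
#'
#' @param instruments numeric `n x m` matrix of instrument genotypes.
#' @param y numeric expression vector.
#' @param lambda_grid positive penalty grid, default [default_ridge_grid()].
#' @return list with `fitted` (length-n vector), `lambda`, `coef`,
#'   `intercept`.
#' @export
stage1_ridge <- function(instruments, y, lambda_grid = default_ridge_grid()) {
  if (length(y) < 2) stop("need at least 2 samples")
  if (is.null(instruments) || NCOL(instruments) == 0) {
    warning("empty instrument set; returning the sample-mean vector")
    return(list(fitted = rep(mean(y), length(y)), lambda = NA_real_,
                coef = numeric(0), intercept = mean(y)))
  }
  instruments <- as.matrix(instruments)
  if (nrow(instruments) != length(y)) {
    stop("instruments and y have different sample counts")
  }
  if (any(!is.finite(instruments)) || any(!is.finite(y))) {
    stop("non-finite values in instruments or y")
  }
  fit <- ridge_fit(instruments, y, lambda_grid)
  list(fitted = fit$fitted, lambda = fit$lambda, coef = fit$coef,
       intercept = fit$intercept)
}
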