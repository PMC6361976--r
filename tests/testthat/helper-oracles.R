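# Independent oracles used across the suite.  These are deliberately naive
# re-derivations (enumeration, union-find, closed forms, lm()) and share no
# code with the implementation they check.

# greedy correlation-pruned selection, re-derived step by step
oracle_greedy_select <- function(scan, X, alpha = 0.05, corr_max = 0.90,
                                 max_k = 3) {
  sig <- scan[scan$p < alpha, , drop = FALSE]
  sig <- sig[order(sig$p, sig$bp), , drop = FALSE]
  kept <- character(0)
  for (m in sig$marker_id) {
    if (length(kept) == max_k) break
    ok <- TRUE
    for (k in kept) if (abs(cor(X[, m], X[, k])) >= corr_max) ok <- FALSE
    if (ok) kept <- c(kept, m)
  }
  kept
}

# weakly connected components by union-find with path compression
oracle_components <- function(edges) {
  nodes <- sort(unique(c(edges$regulator, edges$target)))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$regulator[k], nodes))
    b <- find(match(edges$target[k], nodes))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  unname(lapply(split(nodes, roots), sort))
}

# global minimum of the weighted-lasso objective by enumerating all 3^d
# sign patterns (each pattern gives a linear stationarity system)
oracle_lasso <- function(D, y, w, lambda, unpenalized = integer(0)) {
  n <- nrow(D)
  d <- ncol(D)
  ww <- w
  ww[unpenalized] <- 0
  obj <- function(b) sum((y - D %*% b)^2) / (2 * n) + lambda * sum(ww * abs(b))
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), d)))
  best <- list(v = obj(numeric(d)), b = numeric(d))
  for (i in seq_len(nrow(patterns))) {
    s <- patterns[i, ]
    A <- which(s != 0)
    if (length(A) == 0) next
    DA <- D[, A, drop = FALSE]
    G <- crossprod(DA) / n
    cv <- crossprod(DA, y) / n
    sol <- tryCatch(solve(G, cv - lambda * ww[A] * s[A]),
                    error = function(e) NULL)
    if (is.null(sol)) next
    sol <- as.vector(sol)
    if (any(sign(sol) != s[A])) next
    b <- numeric(d)
    b[A] <- sol
    v <- obj(b)
    if (v < best$v) best <- list(v = v, b = b)
  }
  best$b
}

lasso_objective <- function(D, y, b, w, lambda, unpenalized = integer(0)) {
  ww <- w
  ww[unpenalized] <- 0
  sum((y - D %*% b)^2) / (2 * nrow(D)) + lambda * sum(ww * abs(b))
}

# per-marker simple regression through lm()/summary(), the reference path
oracle_scan_lm <- function(y, X) {
  t(vapply(seq_len(ncol(X)), function(j) {
    s <- summary(lm(y ~ X[, j]))$coefficients
    c(slope = s[2, 1], t = s[2, 3], p = s[2, 4])
  }, c(slope = 0, t = 0, p = 0)))
}

# random orthonormal n x d design (n >= d)
random_orthonormal <- function(n, d) {
  qr.Q(qr(matrix(rnorm(n * d), n, d)))[, seq_len(d), drop = FALSE] * sqrt(n)
}
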