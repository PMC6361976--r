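# Mean imputation, cis windows, the per-marker scan, and the greedy filter.

test_that("impute_missing replaces NAs by observed column means only", {
  map <- data.frame(marker_id = c("a", "b"), chrom = "chr01", cm = c(0, 10),
                    bp = c(100, 200))
  X <- cbind(a = c(0, 1, NA, 1), b = c(1, 0, 0, 1))
  g <- genotype_matrix(X, map)
  imp <- impute_missing(g)
  expect_equal(unname(imp$X[3, "a"]), 2 / 3)
  expect_identical(imp$X[, "b"], g$X[, "b"])  # untouched column

  complete <- genotype_matrix(cbind(a = c(0, 1, 1, 1), b = c(1, 0, 0, 1)), map)
  expect_identical(impute_missing(complete), complete)

  allna <- genotype_matrix(cbind(a = c(NA, NA, NA, NA), b = c(1, 0, 0, 1)), map)
  expect_error(impute_missing(allna), "a")
})

test_that("imputation preserves observed column means (property)", {
  set.seed(5)
  for (rep in 1:20) {
    g <- simulate_segregant_genotypes(40, sim_marker_map(1, 10),
                                      seed = 100 + rep)
    gm <- inject_missing_genotypes(g, runif(1, 0.05, 0.4), seed = rep)
    imp <- impute_missing(gm)
    expect_equal(colMeans(imp$X), colMeans(gm$X, na.rm = TRUE))
    obs <- !is.na(gm$X)
    expect_identical(imp$X[obs], gm$X[obs])
  }
})

test_that("cis_window is strand-aware, clamped, and validated", {
  plus <- list(gene_id = "g", chrom = "c", start = 1000, end = 2000,
               strand = "+")
  minus <- list(gene_id = "g", chrom = "c", start = 1000, end = 2000,
                strand = "-")
  expect_equal(cis_window(plus)[c("start", "end")], list(start = 500, end = 2000))
  expect_equal(cis_window(minus)[c("start", "end")], list(start = 1000, end = 2500))
  near0 <- list(gene_id = "g", chrom = "c", start = 200, end = 900,
                strand = "+")
  expect_equal(cis_window(near0)$start, 0)
  # strand-ignorant replication mode extends before start regardless
  expect_equal(cis_window(minus, strand_aware = FALSE)[c("start", "end")],
               list(start = 500, end = 2000))
  expect_error(cis_window(plus, upstream_bp = -1), "non-negative")
})

test_that("scan_cis_eqtl matches lm() to 1e-10 and handles edge cases", {
  set.seed(42)
  n <- 80
  X <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
              dimnames = list(NULL, paste0("m", 1:6)))
  y <- 0.8 * X[, 2] + rnorm(n)
  got <- scan_cis_eqtl(y, X)
  ref <- oracle_scan_lm(y, X)
  expect_equal(got$slope, unname(ref[, "slope"]), tolerance = 1e-10)
  expect_equal(got$t, unname(ref[, "t"]), tolerance = 1e-10)
  expect_equal(got$p, unname(ref[, "p"]), tolerance = 1e-10)

  # strong signal: slope ~ 2, p << 0.05
  x <- rbinom(100, 1, 0.5)
  y2 <- 2 * x + rnorm(100, sd = 0.05)
  s <- scan_cis_eqtl(y2, cbind(m1 = x))
  expect_lt(abs(s$slope - 2), 0.05)
  expect_lt(s$p, 1e-10)

  # exactly orthogonal y: slope 0, p = 1
  xo <- c(rep(0, 10), rep(1, 10))
  yo <- rep(c(-1, 1), 10)  # cor(xo, yo) == 0 by construction
  so <- scan_cis_eqtl(yo, cbind(m1 = xo))
  expect_equal(so$slope, 0)
  expect_equal(so$p, 1)

  # zero-variance marker skipped with warning; n < 3 rejected
  expect_warning(sz <- scan_cis_eqtl(y, cbind(X, mz = rep(1, n))), "mz")
  expect_false("mz" %in% sz$marker_id)
  expect_error(scan_cis_eqtl(c(1, 2), matrix(0:1, 2, 1)), "3 samples")
})

test_that("select_cis_eqtl reproduces the hand-enumerated greedy example", {
  # markers 1 and 2 highly correlated (|r| >= 0.95); all other pairs weak
  set.seed(7)
  n <- 400
  m1 <- rbinom(n, 1, 0.5)
  m2 <- m1
  m2[c(10, 110, 210, 310)] <- 1 - m2[c(10, 110, 210, 310)]  # 1% discordance
  X <- cbind(m1 = m1, m2 = m2, m3 = rbinom(n, 1, 0.5),
             m4 = rbinom(n, 1, 0.5), m5 = rbinom(n, 1, 0.5))
  stopifnot(abs(cor(X[, 1], X[, 2])) >= 0.95)
  C <- abs(cor(X))
  stopifnot(max(C[upper.tri(C)][-1]) < 0.5)

  scan <- data.frame(marker_id = colnames(X), bp = 1:5 * 1000,
                     slope = 1, t = 1,
                     p = c(.001, .002, .01, .2, .03))
  sel <- select_cis_eqtl(scan, X, alpha = 0.05, corr_max = 0.90, max_k = 3)
  expect_identical(sel$marker_id, c("m1", "m3", "m5"))
  expect_identical(sel$rank, 1:3)

  # single significant marker selected; none significant -> empty
  one <- data.frame(marker_id = "m1", bp = 1, slope = 1, t = 1, p = 0.01)
  expect_identical(select_cis_eqtl(one, X)$marker_id, "m1")
  none <- transform(scan, p = pmax(p, 0.06))
  expect_identical(nrow(select_cis_eqtl(none, X)), 0L)
})

test_that("greedy filter matches the oracle and honours its invariants (property)", {
  set.seed(11)
  for (rep in 1:60) {
    inst <- random_filter_instance()
    sel <- select_cis_eqtl(inst$scan, inst$X)
    expect_identical(sel$marker_id,
                     oracle_greedy_select(inst$scan, inst$X))
    expect_lte(nrow(sel), 3)
    if (any(inst$scan$p < 0.05)) {
      sig <- inst$scan[inst$scan$p < 0.05, ]
      best <- sig$marker_id[order(sig$p, sig$bp)][1]
      expect_identical(sel$marker_id[1], best)  # min-p marker always kept
    }
    if (nrow(sel) > 1) {
      C <- abs(cor(inst$X[, sel$marker_id]))
      expect_lt(max(C[upper.tri(C)]), 0.90)
    }
  }
})

test_that("a strong true cis marker (or a >=0.90 proxy) is selected almost always", {
  hits <- 0L
  reps <- 200
  for (r in seq_len(reps)) {
    d <- sim_dataset(n = 112, p = 4, edges_per_gene = 0, noise_sd = 0.3,
                     cis_effect_range = c(1, 1.2), seed = 5000 + r)
    cm <- suppressWarnings(map_cis_eqtl(d$expression, d$genotypes))
    truth_mk <- d$cis_assignment[["G001"]]
    sel <- cm$markers[["G001"]]
    if (is.null(sel)) next
    Ximp <- impute_missing(d$genotypes)$X
    ok <- any(vapply(sel, function(m) {
      any(abs(cor(Ximp[, m], Ximp[, truth_mk, drop = FALSE])) >= 0.90)
    }, logical(1)))
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("map_cis_eqtl assembles a consistent per-gene table", {
  d <- sim_dataset(n = 112, p = 6, seed = 303)
  cm <- map_cis_eqtl(d$expression, d$genotypes)
  expect_s3_class(cm, "cis_eqtl_map")
  expect_true(all(cm$table$p < 0.05))
  expect_true(all(table(cm$table$gene_id) <= 3))
  expect_setequal(cm$nodes, unique(cm$table$gene_id))
  # rank is selection order within each gene
  for (g in cm$nodes) {
    expect_identical(cm$table$rank[cm$table$gene_id == g],
                     seq_len(sum(cm$table$gene_id == g)))
  }
  # misaligned samples rejected, not realigned
  shuffled <- d$genotypes
  perm <- c(2:nrow(shuffled$X), 1)
  shuffled$X <- shuffled$X[perm, ]
  expect_error(map_cis_eqtl(d$expression, shuffled), "not aligned")
})
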