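# Segregant genotype simulation, ground-truth networks, SEM expression.

test_that("co-located markers co-segregate and distant ones recombine freely", {
  map0 <- data.frame(marker_id = c("a", "b"), chrom = "chr01",
                     cm = c(10, 10), bp = c(100, 200))
  g <- simulate_segregant_genotypes(200, map0, seed = 11)
  expect_identical(g$X[, "a"], g$X[, "b"])  # d = 0 forces co-inheritance

  # markers on different chromosomes: recombinant fraction ~ 0.5
  map1 <- data.frame(marker_id = c("a", "b"), chrom = c("chr01", "chr02"),
                     cm = c(0, 0), bp = c(100, 100))
  n <- 10000
  g1 <- simulate_segregant_genotypes(n, map1, seed = 12)
  rf <- mean(g1$X[, 1] != g1$X[, 2])
  expect_lt(abs(rf - 0.5), 3 * sqrt(0.25 / n))

  # adjacent markers 20 cM apart: Haldane r = 0.5 (1 - e^-0.4)
  map2 <- data.frame(marker_id = c("a", "b"), chrom = "chr01",
                     cm = c(0, 20), bp = c(100, 200))
  g2 <- simulate_segregant_genotypes(n, map2, seed = 13)
  r_exp <- 0.5 * (1 - exp(-0.4))
  rf2 <- mean(g2$X[, 1] != g2$X[, 2])
  expect_lt(abs(rf2 - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n))
})

test_that("genotype invariants: allele frequency ~0.5, correlation decays with distance", {
  map <- sim_marker_map(n_chr = 2, markers_per_chr = 6, spacing_cm = 10)
  n <- 8000
  g <- simulate_segregant_genotypes(n, map, seed = 21)
  af <- colMeans(g$X)
  expect_true(all(abs(af - 0.5) < 4 * sqrt(0.25 / n)))

  # correlation between the chr01 anchor and markers at growing distance
  cors <- sapply(2:6, function(k) cor(g$X[, 1], g$X[, k]))
  expect_true(all(diff(cors) < 0))
  expect_true(all(cors > 0))
})

test_that("genotype simulation validates inputs and is deterministic", {
  map <- sim_marker_map(n_chr = 1, markers_per_chr = 4)
  expect_error(simulate_segregant_genotypes(1, map), "n must be")
  bad <- map
  bad$cm <- rev(bad$cm)
  expect_error(simulate_segregant_genotypes(10, bad), "not sorted")
  g1 <- simulate_segregant_genotypes(50, map, seed = 5)
  g2 <- simulate_segregant_genotypes(50, map, seed = 5)
  expect_identical(g1$X, g2$X)
  expect_true(all(g1$X %in% c(0, 1)))
})

test_that("simulate_network: sparsity, stability, determinism", {
  expect_error(simulate_network(1, seed = 1), "p must be")
  expect_identical(simulate_network(10, edges_per_gene = 0, seed = 1),
                   matrix(0, 10, 10))

  gam <- simulate_network(30, edges_per_gene = 2, seed = 42, acyclic = TRUE)
  expect_true(all(diag(gam) == 0))
  expect_true(all(gam[lower.tri(gam, diag = TRUE)] == 0))  # triangular
  expect_equal(det(diag(30) - gam), 1)                     # always invertible
  nz <- abs(gam[gam != 0])
  expect_true(all(nz >= 0.5 & nz <= 1))
  # expected out-degree ~ 2: binomial with p*(p-1) trials
  expect_lt(abs(sum(gam != 0) / 30 - 2),
            4 * sqrt(2 * (1 - 2 / 29) / 30) + 0.5)

  expect_identical(simulate_network(30, 2, seed = 7),
                   simulate_network(30, 2, seed = 7))

  cyc <- simulate_network(20, edges_per_gene = 1.5, effect_low = 0.1,
                          effect_high = 0.3, acyclic = FALSE, seed = 9)
  expect_lt(max(Mod(eigen(cyc, only.values = TRUE)$values)), 1)
})

test_that("generate_expression solves the structural system exactly in noise-free cases", {
  map <- sim_marker_map(n_chr = 1, markers_per_chr = 2, spacing_cm = 50)
  g <- simulate_segregant_genotypes(40, map, seed = 3)
  psi <- matrix(c(1.2, 0, 0, -0.8), 2, 2,
                dimnames = list(map$marker_id, c("G1", "G2")))

  # Gamma = 0, noise ~ 0: Y = X Psi (noise_sd must be > 0; use negligible)
  tr0 <- simulation_truth(matrix(0, 2, 2), psi, noise_sd = 1e-12, seed = 1)
  e0 <- generate_expression(g, tr0)
  expect_equal(unname(e0$Y), unname(g$X %*% psi), tolerance = 1e-8)

  # gamma_12 = gamma_21 = 0.5: closed-form 2x2 inverse (1/0.75) [[1, .5], [.5, 1]]
  gam <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  tr1 <- simulation_truth(gam, psi, noise_sd = 1e-12, seed = 1)
  e1 <- generate_expression(g, tr1)
  expect_equal(unname(e1$Y),
               unname((g$X %*% psi) %*% (matrix(c(1, .5, .5, 1), 2) / 0.75)),
               tolerance = 1e-8)

  # singular I - Gamma rejected with explicit message
  bad <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(simulation_truth(bad, psi, 0.1, 1), "invertible")
  expect_error(
    generate_expression(g, list(gamma = bad, psi = psi, noise_sd = 0.1,
                                seed = 1)),
    "singular")
})

test_that("simulated expression covariance matches the propagation formula", {
  # Cov(Y) = (I-G)^-T (Psi' S_X Psi + sigma^2 I) (I-G)^-1 with S_X empirical.
  # At n = 50000 the MC error of a covariance entry is ~sqrt(2)*scale/sqrt(n),
  # well under the 0.05 band used here (entry scale is O(1)).
  n <- 50000
  p <- 20
  set.seed(99)
  d <- sim_dataset(n = n, p = p, edges_per_gene = 1.5,
                   effect_range = c(0.3, 0.5), noise_sd = 0.4, seed = 99)
  Sx <- cov(d$genotypes$X)
  inv <- solve(diag(p) - d$truth$gamma)
  expected <- t(inv) %*% (t(d$truth$psi) %*% Sx %*% d$truth$psi +
                            diag(d$truth$noise_sd^2, p)) %*% inv
  observed <- cov(d$expression$Y)
  expect_lt(max(abs(observed - expected)), 0.05 * max(1, max(abs(expected))))
})

test_that("with Gamma = 0 and Psi = 0 expression columns are iid Gaussian noise", {
  map <- sim_marker_map(n_chr = 1, markers_per_chr = 3)
  g <- simulate_segregant_genotypes(500, map, seed = 8)
  psi <- matrix(0, 3, 4, dimnames = list(map$marker_id, paste0("G", 1:4)))
  tr <- simulation_truth(matrix(0, 4, 4), psi, noise_sd = 0.7, seed = 31)
  e <- generate_expression(g, tr)
  expect_true(all(apply(e$Y, 2, function(y) shapiro.test(y)$p.value) > 0.01))
  expect_true(all(abs(apply(e$Y, 2, var) - 0.49) < 0.15))
  expect_lt(max(abs(cor(e$Y)[upper.tri(diag(4))])), 0.15)
})

test_that("inject_missing_genotypes: rate, identity, determinism", {
  g <- simulate_segregant_genotypes(100, sim_marker_map(2, 50), seed = 4)
  expect_identical(inject_missing_genotypes(g, 0, seed = 1), g)
  expect_error(inject_missing_genotypes(g, 1, seed = 1), "rate")

  m1 <- inject_missing_genotypes(g, 0.1, seed = 2)
  n_cells <- length(g$X)  # 10,000 cells
  n_miss <- sum(is.na(m1$X))
  expect_lt(abs(n_miss - 0.1 * n_cells), 3 * sqrt(n_cells * 0.1 * 0.9))
  expect_identical(m1$map, g$map)

  m2 <- inject_missing_genotypes(g, 0.1, seed = 2)
  expect_identical(is.na(m1$X), is.na(m2$X))
})

test_that("sim_dataset is fully deterministic and internally consistent", {
  d1 <- sim_dataset(n = 60, p = 8, seed = 77)
  d2 <- sim_dataset(n = 60, p = 8, seed = 77)
  expect_identical(d1$expression$Y, d2$expression$Y)
  expect_identical(d1$genotypes$X, d2$genotypes$X)
  expect_identical(d1$truth$gamma, d2$truth$gamma)

  # psi nonzeros sit exactly at each gene's assigned cis markers, <= 3 each
  nz_per_gene <- colSums(d1$truth$psi != 0)
  expect_true(all(nz_per_gene >= 1 & nz_per_gene <= 3))
  for (g in names(d1$cis_assignment)) {
    nz <- rownames(d1$truth$psi)[d1$truth$psi[, g] != 0]
    expect_setequal(nz, d1$cis_assignment[[g]])
  }
  # gene bodies contain their cis markers (window contract)
  genes <- d1$expression$genes
  map <- d1$genotypes$map
  for (i in seq_len(nrow(genes))) {
    mk <- map[map$marker_id %in% d1$cis_assignment[[genes$gene_id[i]]], ]
    expect_true(all(mk$bp >= genes$start[i] & mk$bp < genes$end[i]))
  }
})
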