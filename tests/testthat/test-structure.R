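test_that("LD pruning drops exact duplicates and respects windows", {
  set.seed(101)
  g <- matrix(rbinom(20 * 10, 2, 0.5), 20)
  g <- cbind(g, g[, 3])  # duplicate of column 3 at position 11
  kept <- ld_prune(g, window = 50, step = 5)
  expect_true(3 %in% kept)
  expect_false(11 %in% kept)

  # correlation invariance: adding a constant to one site changes nothing
  g2 <- g; g2[, 5] <- g2[, 5] + 3L
  expect_identical(ld_prune(g2), kept)

  expect_error(ld_prune(g, window = 2, step = 5), "window")
})

test_that("independent sites survive pruning at the 0.7 threshold", {
  set.seed(111)
  g <- matrix(rbinom(100 * 60, 2, rep(runif(60, 0.2, 0.8), each = 100)),
              100)
  expect_identical(ld_prune(g), seq_len(60))
})

test_that("LD pruning equals the brute-force pair checker", {
  set.seed(121)
  for (r in 1:20) {
    n <- sample(10:25, 1)
    g <- matrix(rbinom(n * 30, 2, rep(runif(30, 0.1, 0.9), each = n)), n)
    # induce correlated blocks so pruning has real work to do
    for (k in sample(2:29, 6))
      if (runif(1) < 0.7) g[, k] <- g[, k - 1] + rbinom(n, 1, 0.1)
    w <- sample(c(6L, 10L, 50L), 1); s <- sample(c(2L, 5L), 1)
    expect_identical(ld_prune(g, w, s, 0.7), brute_force_prune(g, w, s, 0.7))
  }
})

test_that("genotype PCA separates the parental pools", {
  ok <- vapply(1:5, function(r) {
    cfg <- sim_config(n_sites = 500, n_parents_A = 5, n_parents_B = 5,
                      seed = 130 + r)
    sim <- simulate_dataset(cfg)
    dd <- diploidize(sim$genotypes$dosage, sim$genotypes$ploidy)
    pc <- pca_genotypes(dd)
    a <- pc$scores[sim$metadata$morphotype == "parental_A", 1]
    b <- pc$scores[sim$metadata$morphotype == "parental_B", 1]
    max(min(a), min(b)) > min(max(a), max(b))  # disjoint PC1 ranges
  }, logical(1))
  expect_true(all(ok))
})

test_that("PCA output has spectral structure and drops constant sites", {
  set.seed(141)
  g <- matrix(rbinom(12 * 80, 2, 0.4), 12)
  g[, 1] <- 0L  # monomorphic site: no information after centring
  g[3, 7] <- NA  # mean imputation path
  pc <- pca_genotypes(g)
  expect_identical(pc$n_sites, 79L)
  expect_true(all(pc$var_explained >= 0))
  expect_true(all(diff(pc$var_explained) <= 1e-8))
  expect_lte(sum(pc$var_explained), 100 + 1e-8)
  expect_error(pca_genotypes(g[1:2, ]), "3 samples")
})

test_that("admixture fit handles the degenerate single-cluster model", {
  set.seed(151)
  g <- matrix(rbinom(8 * 60, 2, rep(runif(60, 0.2, 0.8), each = 8)), 8)
  fit <- admixture_fit(g, 2L, K = 1, chains = 2, iter = 300, seed = 1)
  expect_true(all(fit$q == 1))
  expect_identical(dim(fit$q), c(8L, 1L))
  expect_true(is.finite(fit$DIC) && is.finite(fit$lppd))
})

test_that("admixture separates pure parental pools at K = 2", {
  # posterior assignments sharpen with cohort and marker count; a
  # well-sampled parental panel concentrates at the simplex vertex
  cfg <- sim_config(n_sites = 4000, n_parents_A = 12, n_parents_B = 12,
                    seed = 161)
  sim <- simulate_dataset(cfg)
  g <- sim$genotypes
  fit <- suppressWarnings(
    admixture_fit(g$dosage, g$ploidy, K = 2, chains = 3,
                  iter = 1500, seed = 7))
  expect_equal(unname(rowSums(fit$q)), rep(1, nrow(fit$q)),
               tolerance = 1e-8)
  expect_true(all(apply(fit$q, 1, max) >= 0.98))
  # mean parental assignment within 0.02 of the (1, 0) vertex
  cm <- map_clusters_to_parents(fit, paste0("A", 1:12), paste0("B", 1:12))
  expect_true(cm["A"] != cm["B"])
  expect_equal(mean(fit$q[paste0("A", 1:12), cm[["A"]]]), 1,
               tolerance = 0.02)
  expect_equal(mean(fit$q[paste0("B", 1:12), cm[["B"]]]), 1,
               tolerance = 0.02)
})

test_that("missing dosages are marginalised, not imputed", {
  set.seed(171)
  g <- matrix(rbinom(6 * 40, 2, 0.5), 6)
  g[cbind(sample(6, 10, TRUE), sample(40, 10, TRUE))] <- NA
  # short exploratory run: convergence warnings are expected and benign
  fit <- suppressWarnings(
    admixture_fit(g, 2L, K = 2, chains = 2, iter = 300, seed = 2))
  expect_true(all(is.finite(fit$q)))
  expect_equal(unname(rowSums(fit$q)), rep(1, 6), tolerance = 1e-8)
})

test_that("K selection minimises DIC with ties toward smaller K", {
  f1 <- structure(list(K = 1L, DIC = 100, lppd = -50, p_D = 2),
                  class = "ancestry_fit")
  f2 <- structure(list(K = 2L, DIC = 90, lppd = -45, p_D = 4),
                  class = "ancestry_fit")
  f3 <- structure(list(K = 3L, DIC = 90, lppd = -45, p_D = 6),
                  class = "ancestry_fit")
  sel <- select_K(list(f3, f1, f2))  # order-independent
  expect_identical(sel$K, 2L)
  expect_identical(sel$table$K, 1:3)
  expect_error(select_K(list(f1)), "at least 2")
})
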