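test_that("shared heterozygosity counts jointly heterozygous sites", {
  a <- c(1L, 1L, 1L, 1L, 0L, 2L)  # het at sites 1-4
  b <- c(1L, 1L, 0L, 2L, 1L, 2L)  # het at 1, 2, 5
  expect_equal(shared_heterozygosity(a, b), 2 / 4)
  expect_equal(shared_heterozygosity(b, a), 2 / 4)  # symmetric

  v <- c(0L, 1L, 2L, 1L)
  expect_equal(shared_heterozygosity(v, v), 1)
  expect_equal(shared_heterozygosity(c(0L, 2L), c(0L, 2L)), 0)  # no hets
  expect_error(shared_heterozygosity(a, b[-1]), "length")

  # pairwise missing exclusion: site 1 missing in b drops it from both,
  # leaving a het at {2} vs b het at {2, 3} -> 1/2
  am <- c(1L, 1L, 0L); bm <- c(NA, 1L, 1L)
  expect_equal(shared_heterozygosity(am, bm), 1 / 2)
})

test_that("shared heterozygosity matches a naive counting oracle", {
  set.seed(31)
  for (r in 1:25) {
    J <- sample(20:60, 1)
    a <- sample(c(0:2, NA), J, replace = TRUE)
    b <- sample(c(0:2, NA), J, replace = TRUE)
    expect_equal(shared_heterozygosity(a, b), naive_sh(a, b))
    expect_true(shared_heterozygosity(a, b) >= 0 &&
                  shared_heterozygosity(a, b) <= 1)
  }
})

test_that("clone pairs keep SH above the clonality threshold under noise", {
  set.seed(41)
  worst <- 1
  for (r in 1:20) {
    f <- runif(10000, 0.05, 0.95)
    founder <- rbinom(10000, 4, f)
    cl <- clone_with_error(founder, 4L, 0.005, 0.02, n_clones = 2)
    dd <- diploidize(rbind(founder, cl$dosage), 4L)
    sh <- shared_heterozygosity(dd[2, ], dd[3, ])
    worst <- min(worst, sh)
  }
  expect_gt(worst, 0.90)
})

test_that("moments IBD recovers the canonical pedigree expectations", {
  set.seed(51)
  J <- 10000
  f <- runif(J, 0.05, 0.95)
  n_bg <- 14
  bg <- matrix(rbinom(n_bg * J, 2, rep(f, each = n_bg)), n_bg)

  # identical genotypes: PI_HAT at the self-comparison limit
  ac <- colSums(bg); nc <- rep(2L * n_bg, J)
  self <- ibd_moments(bg[1, ], bg[1, ], ac, nc)
  expect_gte(self$PI_HAT, 0.99)
  expect_equal(self$Z0 + self$Z1 + self$Z2, 1)

  # unrelated pairs from one Hardy-Weinberg population: mean near 0
  un <- replicate(30, {
    g <- matrix(rbinom(2 * J, 2, rep(f, each = 2)), 2)
    all_g <- rbind(g, bg)
    ibd_moments(g[1, ], g[2, ], colSums(all_g), rep(2L * (n_bg + 2), J))$PI_HAT
  })
  expect_lt(mean(un), 0.05)

  # parent-offspring: one allele shared IBD everywhere, PI_HAT ~ 0.5
  po <- replicate(20, {
    mo <- rbinom(J, 2, f); fa <- rbinom(J, 2, f)
    off <- rhyper(J, mo, 2 - mo, 1) + rhyper(J, fa, 2 - fa, 1)
    all_g <- rbind(mo, fa, off, bg)
    ibd_moments(mo, off, colSums(all_g), rep(2L * (n_bg + 3), J))$PI_HAT
  })
  expect_equal(mean(po), 0.5, tolerance = 0.05 / 0.5)
})

test_that("IBD degrades monotonically with clone genotyping error", {
  set.seed(61)
  J <- 8000
  mean_pi <- vapply(c(0, 0.005, 0.02), function(eps) {
    mean(replicate(5, {
      f <- runif(J, 0.05, 0.95)
      founder <- rbinom(J, 4, f)
      cl <- clone_with_error(founder, 4L, eps, 0, n_clones = 2)
      dd <- diploidize(rbind(founder, cl$dosage,
                             matrix(rbinom(10 * J, 4, rep(f, each = 10)),
                                    10)), 4L)
      ac <- colSums(dd); nc <- rep(2L * nrow(dd), J)
      ibd_moments(dd[2, ], dd[3, ], ac, nc)$PI_HAT
    }))
  }, numeric(1))
  expect_true(all(diff(mean_pi) < 0))
  expect_true(mean_pi[1] > 0.999)  # noise-free clones are fully IBD
})

test_that("IBD estimates carry site-count guardrails", {
  set.seed(71)
  g <- matrix(rbinom(2 * 50, 2, 0.5), 2)
  bg <- matrix(rbinom(10 * 50, 2, 0.5), 10)
  ac <- colSums(rbind(g, bg)); nc <- rep(24L, 50)
  r <- ibd_moments(g[1, ], g[2, ], ac, nc)
  expect_true(r$low_confidence)
  expect_true(r$PI_HAT >= 0 && r$PI_HAT <= 1)
  expect_error(ibd_moments(1:3, 1:4, rep(1, 3), rep(2, 3)), "length")
})

test_that("clone calling groups by IBD transitive closure", {
  set.seed(81)
  J <- 4000
  f <- runif(J, 0.1, 0.9)
  founder <- rbinom(J, 4, f)
  cl <- clone_with_error(founder, 4L, 0.005, 0.02, n_clones = 4)
  unrel <- matrix(rbinom(3 * J, 4, rep(f, each = 3)), 3)
  geno <- rbind(founder, cl$dosage, unrel)
  rownames(geno) <- c("F0", paste0("c", 1:4), paste0("U", 1:3))
  dd <- diploidize(geno, 4L)
  rel <- relatedness_table(dd)
  grp <- call_clones(rel)
  expect_identical(sort(grp$sample[grp$clone_group == "F0"]),
                   sort(c("F0", paste0("c", 1:4))))
  expect_identical(grp$clone_group[grp$sample %in% paste0("U", 1:3)],
                   paste0("U", 1:3))
  # unreachable threshold: everything is a singleton
  grp2 <- call_clones(rel, ibd_threshold = 1.01)
  expect_identical(grp2$clone_group, grp2$sample)
})

test_that("triploid full sibs stay below the clonality threshold", {
  set.seed(91)
  co <- clonality_cohort(n_sites = 6000, seed = 91, n_clones = 2,
                         with_relatives = TRUE)
  st <- clonality_stats(co)
  expect_lt(st$sib_PI, 0.95)
  expect_lt(st$po_PI, 0.95)
  expect_true(all(st$clone_PI > 0.95))
})
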