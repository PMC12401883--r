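test_that("parental pools follow the divergence model", {
  # no-drift limit: pools collapse onto the ancestral frequency
  cfg_lo <- sim_config(n_sites = 5000, divergence = 0.005, seed = 1)
  set.seed(1)
  lo <- simulate_parental_pools(cfg_lo)
  expect_lt(mean(abs(lo$f_A - lo$f_B)), 0.08)

  # divergence parameter recovered by an independent Hudson estimator
  cfg <- sim_config(n_sites = 10000, divergence = 0.3, seed = 2)
  set.seed(2)
  pools <- simulate_parental_pools(cfg)
  expect_true(all(pools$f_A >= 0 & pools$f_A <= 1))
  expect_equal(hudson_fst(pools$f_A, pools$f_B), 0.3, tolerance = 0.05 / 0.3)

  # determinism under a fixed seed
  set.seed(7); a <- simulate_parental_pools(cfg)
  set.seed(7); b <- simulate_parental_pools(cfg)
  expect_identical(a, b)

  expect_error(sim_config(divergence = 0), "divergence")
  expect_error(sim_config(divergence = 1.2), "divergence")
})

test_that("genotype draws are binomial in the pool frequency", {
  cfg <- sim_config(n_sites = 50, seed = 3)
  set.seed(3)
  pools <- simulate_parental_pools(cfg)
  fixed <- pools
  fixed$f_A <- rep(1 - 1e-12, 50)
  g <- draw_genotypes(fixed, 4L, "A", 10)
  expect_true(all(g$dosage == 4L))

  half <- pools
  half$f_B <- rep(0.5, 50)
  set.seed(4)
  g2 <- draw_genotypes(half, 2L, "B", 400)
  expect_equal(mean(g2$dosage), 1.0, tolerance = 0.02)

  expect_error(draw_genotypes(pools, 3L, "A", 2), "ploidy")
})

test_that("hybrid formation respects gamete arithmetic", {
  J <- 200
  mo <- rep(2L, J)  # diploid mother, homozygous alt
  fa <- rep(0L, J)  # tetraploid father, homozygous ref
  off <- form_hybrid(mo, 2L, fa, 4L, "reduced", "reduced")
  expect_identical(off$ploidy, 3L)
  expect_true(all(off$dosage == 1L))  # forced segregation

  off4 <- form_hybrid(mo, 2L, fa, 4L, "unreduced", "reduced")
  expect_identical(off4$ploidy, 4L)
  expect_true(all(off4$dosage == 2L))

  expect_error(
    form_hybrid(c(0L, 1L, 2L), 3L, fa[1:3], 4L, "reduced", "reduced"),
    "even")

  # dosage conservation over random parents
  set.seed(11)
  for (r in 1:20) {
    m <- sample(0:2, J, replace = TRUE)
    f <- sample(0:4, J, replace = TRUE)
    mode_m <- sample(c("reduced", "unreduced"), 1)
    o <- form_hybrid(m, 2L, f, 4L, mode_m, "reduced")
    expect_true(all(o$dosage <= o$ploidy))
    expect_true(all(o$dosage <= m + f))
  }
})

test_that("clonal replicates carry calibrated noise", {
  founder <- rep(c(0L, 1L, 2L, 3L, 4L), each = 2000)
  cl <- clone_with_error(founder, 4L, error_rate = 0, missing_rate = 0,
                         n_clones = 3, seed = 5)
  expect_true(all(t(cl$dosage) == founder))

  cl2 <- clone_with_error(founder, 4L, error_rate = 0.005,
                          missing_rate = 0, n_clones = 1, seed = 6)
  n_perturbed <- sum(cl2$dosage[1, ] != founder)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.005)
  expect_gte(n_perturbed, ci[1])
  expect_lte(n_perturbed, ci[2])
  # errors always move to another legal dosage
  expect_true(all(cl2$dosage >= 0 & cl2$dosage <= 4))

  expect_error(clone_with_error(founder, 4L, missing_rate = 1), "rates")
})

test_that("the full generator is deterministic and internally consistent", {
  cfg <- sim_config(n_sites = 300, n_parents_A = 3, n_parents_B = 3,
                    hybrids = c(triploid_F1 = 2,
                                tetraploid_unreduced_F1 = 2,
                                diploid_introgressant = 1),
                    clones = c(H3 = 2), n_indels = 4, seed = 42)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim1, sim2)

  m <- sim1$metadata
  expect_identical(m$ploidy[m$morphotype == "triploid_F1"], rep(3L, 2))
  # clones of H3 inherit its morphotype, so 4 tetraploid-F1 rows in all
  expect_identical(m$ploidy[m$morphotype == "tetraploid_unreduced_F1"],
                   rep(4L, 4))
  expect_identical(m$ploidy[m$morphotype == "diploid_introgressant"], 2L)
  expect_identical(m$clone_group[m$sample %in% c("H3", "H3_c1", "H3_c2")],
                   rep("H3", 3))
  # maternal plastome inheritance: nearer to the maternal pool reference
  d_A <- rowSums(sim1$plastomes != matrix(sim1$plastome_refs$A,
                                          nrow(sim1$plastomes),
                                          cfg$plastome_length, byrow = TRUE))
  d_B <- rowSums(sim1$plastomes != matrix(sim1$plastome_refs$B,
                                          nrow(sim1$plastomes),
                                          cfg$plastome_length, byrow = TRUE))
  expect_true(all((d_A < d_B) == (m$maternal_pool == "A")))
})

test_that("VCF emission round-trips and is byte-stable", {
  cfg <- sim_config(n_sites = 150, n_parents_A = 3, n_parents_B = 3,
                    hybrids = c(triploid_F1 = 2), n_indels = 3, seed = 9)
  sim <- simulate_dataset(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_sim_vcf(sim, d1)
  p2 <- write_sim_vcf(simulate_dataset(cfg), d2)
  expect_identical(readBin(p1["vcf"], "raw", 1e6),
                   readBin(p2["vcf"], "raw", 1e6))

  v <- read_dosage_vcf(p1["vcf"])
  expect_identical(sum(v$sites$type == "indel"), 3L)
  snp <- v$sites$type == "SNP"
  expect_identical(unname(v$dosage[, snp]),
                   unname(sim$genotypes$dosage))
  expect_identical(unname(v$ploidy), sim$genotypes$ploidy)
  # triploid GT strings carry three alleles
  expect_identical(max(v$ploidy[grepl("^H", names(v$ploidy))]), 3L)
})

test_that("an all-nominal cohort passes the filter cascade in full", {
  cfg <- sim_config(n_sites = 200, n_parents_A = 3, n_parents_B = 3,
                    fail_fraction = 0, n_indels = 0, seed = 10)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  v <- read_dosage_vcf(write_sim_vcf(sim, dir)["vcf"])
  fr <- filter_variants(v)
  expect_identical(fr$report$retained_sites, rep(200L, 4))
  expect_identical(sum(is.na(fr$dosage)), sum(is.na(sim$genotypes$dosage)))
})
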