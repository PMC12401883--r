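# Independent oracles and fixture builders shared across tests.

# Brute-force sliding-window LD pruner: explicit loops over every
# within-window ordered pair, dropping the later site when r^2 exceeds
# the threshold. Mirrors the documented window semantics but shares no
# code with ld_prune().
brute_force_prune <- function(geno, window = 50L, step = 5L,
                              r2_threshold = 0.7) {
  J <- ncol(geno)
  keep <- rep(TRUE, J)
  if (J < 2L) return(which(keep))
  for (s in seq(1L, max(1L, J - 1L), by = step)) {
    win <- s:min(s + window - 1L, J)
    for (jj in win) {
      for (ii in win[win < jj]) {
        if (!keep[ii] || !keep[jj]) next
        r <- suppressWarnings(
          stats::cor(geno[, ii], geno[, jj],
                     use = "pairwise.complete.obs"))
        if (is.finite(r) && r^2 > r2_threshold) keep[jj] <- FALSE
      }
    }
  }
  which(keep)
}

# Naive per-site counting oracle for the shared-heterozygosity index.
naive_sh <- function(a, b) {
  ha <- 0L; hb <- 0L; joint <- 0L
  for (s in seq_along(a)) {
    if (is.na(a[s]) || is.na(b[s])) next
    if (a[s] == 1L) ha <- ha + 1L
    if (b[s] == 1L) hb <- hb + 1L
    if (a[s] == 1L && b[s] == 1L) joint <- joint + 1L
  }
  if (max(ha, hb) == 0L) return(0)
  joint / max(ha, hb)
}

# Hudson-style Fst from the two pool allele-frequency vectors
# (ratio-of-averages estimator).
hudson_fst <- function(f_a, f_b) {
  mean((f_a - f_b)^2) / mean(f_a * (1 - f_b) + f_b * (1 - f_a))
}

# Hand-built VCF of 10 biallelic SNPs for 2 diploid samples where
# exactly 4 records each violate one named hard-filter threshold
# (QD < 10, FS > 60, SOR > 3, MQ < 40) and the other 6 are nominal.
# Mean depth is 700, so the DP cutoff is 1400; all DP values sit below.
# Hand enumeration: survivors are records 1, 3, 5, 7, 9, 10.
violation_fixture_vcf <- function(path) {
  info <- function(qd, fs, sor, mq, mqrs, dp, rprs)
    sprintf("QD=%.1f;FS=%.1f;SOR=%.1f;MQ=%.1f;MQRankSum=%.1f;DP=%d;ReadPosRankSum=%.1f",
            qd, fs, sor, mq, mqrs, dp, rprs)
  nominal <- info(25, 5, 1.0, 55, 0.0, 700L, 0.0)
  infos <- c(nominal,                            # 1 pass
             info(5, 5, 1.0, 55, 0, 700L, 0),    # 2 fail QD
             nominal,                            # 3 pass
             info(25, 80, 1.0, 55, 0, 700L, 0),  # 4 fail FS
             nominal,                            # 5 pass
             info(25, 5, 4.5, 55, 0, 700L, 0),   # 6 fail SOR
             nominal,                            # 7 pass
             info(25, 5, 1.0, 30, 0, 700L, 0),   # 8 fail MQ
             nominal, nominal)                   # 9, 10 pass
  pos <- seq(100L, by = 50L, length.out = 10L)
  recs <- sprintf("chr1\t%d\t.\tA\tG\t.\tPASS\t%s\tGT:GQ:DP\t0/1:80:40\t0/0:80:40",
                  pos, infos)
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=1000>",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"x\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"x\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2")
  writeLines(c(hdr, recs), path)
  path
}
violation_fixture_survivors <- c(1L, 3L, 5L, 7L, 9L, 10L)

# Cohort used by the clonality acceptance checks: 10 unrelated parents
# (5 diploid pool-A, 5 tetraploid pool-B), a tetraploid unreduced-
# gamete F1 founder with `n_clones` noisy clonal replicates, plus
# optionally a triploid full-sib pair (same two parents) and a diploid
# parent-offspring pair. Returns the dosage matrix, ploidy and the
# index sets of the comparison pairs.
clonality_cohort <- function(n_sites = 10000L, seed = 1L,
                             n_clones = 5L, with_relatives = TRUE) {
  cfg <- sim_config(n_sites = n_sites, seed = seed)
  set.seed(seed)
  pools <- simulate_parental_pools(cfg)
  pa <- draw_genotypes(pools, 2L, "A", 5L)
  pb <- draw_genotypes(pools, 4L, "B", 5L)
  founder <- form_hybrid(pa$dosage[1, ], 2L, pb$dosage[1, ], 4L,
                         "unreduced", "reduced")
  clones <- clone_with_error(founder$dosage, founder$ploidy,
                             error_rate = cfg$error_rate,
                             missing_rate = cfg$missing_rate,
                             n_clones = n_clones)
  geno <- rbind(pa$dosage, pb$dosage, founder$dosage, clones$dosage)
  ploidy <- c(pa$ploidy, pb$ploidy, founder$ploidy, clones$ploidy)
  ids <- c(paste0("A", 1:5), paste0("B", 1:5), "F0",
           paste0("F0_c", seq_len(n_clones)))
  clone_idx <- 10L + seq_len(n_clones + 1L)
  sib_idx <- po_idx <- NULL
  if (with_relatives) {
    sib1 <- form_hybrid(pa$dosage[2, ], 2L, pb$dosage[2, ], 4L)
    sib2 <- form_hybrid(pa$dosage[2, ], 2L, pb$dosage[2, ], 4L)
    child <- form_hybrid(pa$dosage[3, ], 2L, pa$dosage[4, ], 2L)
    geno <- rbind(geno, sib1$dosage, sib2$dosage, child$dosage)
    ploidy <- c(ploidy, sib1$ploidy, sib2$ploidy, child$ploidy)
    ids <- c(ids, "sib1", "sib2", "child")
    n <- length(ids)
    sib_idx <- c(n - 2L, n - 1L)
    po_idx <- c(3L, n)  # A3 and its offspring
  }
  rownames(geno) <- ids
  list(geno = geno, ploidy = ploidy, clone_idx = clone_idx,
       sib_idx = sib_idx, po_idx = po_idx)
}

# SH and moments-IBD statistics for the designated pairs of a
# clonality cohort: SH on the full diploidized matrix, IBD on the
# LD-pruned subset, frequencies from all samples.
clonality_stats <- function(cohort) {
  dd <- diploidize(cohort$geno, cohort$ploidy)
  pruned <- dd[, ld_prune(dd), drop = FALSE]
  ac <- colSums(pruned, na.rm = TRUE)
  nc <- 2 * colSums(!is.na(pruned))
  pair_stats <- function(i, j)
    c(SH = shared_heterozygosity(dd[i, ], dd[j, ]),
      PI_HAT = ibd_moments(pruned[i, ], pruned[j, ], ac, nc)$PI_HAT)
  cp <- utils::combn(cohort$clone_idx, 2)
  clone <- t(apply(cp, 2, function(p) pair_stats(p[1], p[2])))
  out <- list(clone_SH = clone[, "SH"], clone_PI = clone[, "PI_HAT"])
  if (!is.null(cohort$sib_idx))
    out$sib_PI <- pair_stats(cohort$sib_idx[1],
                             cohort$sib_idx[2])[["PI_HAT"]]
  if (!is.null(cohort$po_idx))
    out$po_PI <- pair_stats(cohort$po_idx[1],
                            cohort$po_idx[2])[["PI_HAT"]]
  out
}
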