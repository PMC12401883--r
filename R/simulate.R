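#' Configuration for the mixed-ploidy cohort simulator
#'
#' Collects and validates the parameters of the synthetic-data generator.
#' The generator emulates the statistical structure of a hybrid plant
#' complex after variant calling: two diverged parental gene pools (a
#' diploid and an autotetraploid species), interploidy F1 hybrids, clonal
#' replicates carrying genotyping error and missingness, and maternally
#' inherited plastome haplotypes.
#'
#' Parental divergence follows the Balding-Nichols construction: each
#' site's ancestral frequency is uniform on (0.05, 0.95) and each pool
#' draws its own frequency from a Beta distribution whose spread is set by
#' the drift parameter `divergence` (the expected Fst between the pools).
#'
#' @param n_sites number of biallelic SNP sites (default 10000).
#' @param divergence Balding-Nichols drift parameter F in (0,1); expected
#'   Fst between the parental pools (default 0.3, two well-separated
#'   congeners).
#' @param n_parents_A,n_parents_B numbers of diploid pool-A and
#'   tetraploid pool-B parental samples.
#' @param hybrids named integer vector: counts per hybrid cytotype, names
#'   among `"triploid_F1"`, `"tetraploid_unreduced_F1"`,
#'   `"diploid_introgressant"`.
#' @param clones named integer vector: numbers of clonal replicates keyed
#'   by founder sample id (founders are named `A1..`, `B1..`, `H1..`).
#' @param error_rate per-site genotyping error rate for clonal replicates
#'   in `[0,1)` (default 0.005).
#' @param missing_rate per-call missingness rate in `[0,1)` (default 0.02).
#' @param fail_fraction fraction of sites given annotation values beyond
#'   the hard-filter thresholds (default 0.1).
#' @param n_indels number of indel records interleaved in the emitted VCF.
#' @param mean_depth nominal mean site depth used to draw DP annotations.
#' @param plastome_length,plastome_diag_sites,plastome_error length of the
#'   simulated plastome haplotypes, number of diagnostic differences
#'   between the parental references, and per-base copying error.
#' @param seed integer random seed; a fixed seed makes the generator's
#'   output byte-identical across runs.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_sites = 10000L,
                       divergence = 0.3,
                       n_parents_A = 5L,
                       n_parents_B = 5L,
                       hybrids = c(),
                       clones = c(),
                       error_rate = 0.005,
                       missing_rate = 0.02,
                       fail_fraction = 0.1,
                       n_indels = 0L,
                       mean_depth = 713.1,
                       plastome_length = 2000L,
                       plastome_diag_sites = 40L,
                       plastome_error = 1e-3,
                       seed = 1L) {
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) stop("`n_sites` must be >= 1")
  if (!is.numeric(divergence) || divergence <= 0 || divergence >= 1)
    stop("`divergence` must lie in (0, 1)")
  for (r in c(error_rate, missing_rate, fail_fraction))
    if (r < 0 || r >= 1) stop("rates must lie in [0, 1)")
  if (length(hybrids))
    stopifnot(all(names(hybrids) %in%
                    c("triploid_F1", "tetraploid_unreduced_F1",
                      "diploid_introgressant")))
  if (length(clones) && is.null(names(clones)))
    stop("`clones` must be named by founder sample id")
  structure(list(
    n_sites = n_sites, divergence = divergence,
    n_parents_A = as.integer(n_parents_A),
    n_parents_B = as.integer(n_parents_B),
    hybrids = hybrids, clones = clones,
    error_rate = error_rate, missing_rate = missing_rate,
    fail_fraction = fail_fraction, n_indels = as.integer(n_indels),
    mean_depth = mean_depth,
    plastome_length = as.integer(plastome_length),
    plastome_diag_sites = as.integer(plastome_diag_sites),
    plastome_error = plastome_error,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate diverged parental allele-frequency pools
#'
#' Balding-Nichols model: per site an ancestral frequency
#' p ~ Uniform(0.05, 0.95), then each pool's alternate-allele frequency is
#' drawn independently from Beta(p(1-F)/F, (1-p)(1-F)/F), so the expected
#' Fst between pools equals the drift parameter F.
#'
#' @param config a [sim_config()].
#' @return List of class `parental_pools` with per-site vectors `p_anc`,
#'   `f_A`, `f_B`.
#' @export
simulate_parental_pools <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  F <- config$divergence
  J <- config$n_sites
  p <- stats::runif(J, 0.05, 0.95)
  shape <- (1 - F) / F
  f_A <- stats::rbeta(J, p * shape, (1 - p) * shape)
  f_B <- stats::rbeta(J, p * shape, (1 - p) * shape)
  # guard against numerically fixed sites so binomial draws stay informative
  eps <- 1e-9
  structure(list(p_anc = p,
                 f_A = pmin(pmax(f_A, eps), 1 - eps),
                 f_B = pmin(pmax(f_B, eps), 1 - eps)),
            class = "parental_pools")
}

#' Draw unrelated genotypes from one parental pool
#'
#' Dosage at each site is Binomial(ploidy, pool frequency), independent
#' across sites and samples (sites are exchangeable; no linkage).
#'
#' @param pools a [simulate_parental_pools()] result.
#' @param ploidy 2 (diploid pool) or 4 (autotetraploid pool).
#' @param pool `"A"` or `"B"`.
#' @param n number of samples.
#' @return A [dosage_matrix()].
#' @export
draw_genotypes <- function(pools, ploidy, pool = c("A", "B"), n) {
  stopifnot(inherits(pools, "parental_pools"))
  pool <- match.arg(pool)
  if (!ploidy %in% c(2L, 4L)) stop("`ploidy` must be 2 or 4")
  f <- if (pool == "A") pools$f_A else pools$f_B
  J <- length(f)
  g <- matrix(stats::rbinom(n * J, ploidy, rep(f, each = n)), nrow = n)
  dosage_matrix(g, rep(as.integer(ploidy), n))
}

# Dosage carried by one gamete: `reduced` samples m/2 of the parent's m
# allele copies without replacement (random bivalent pairing, so a
# hypergeometric draw on the dosage); `unreduced` passes all m copies.
# `n_copies` overrides the reduced copy number (used for single-copy
# gametes of introgressant crosses).
gamete_dosage <- function(dosage, ploidy, mode = c("reduced", "unreduced"),
                          n_copies = NULL) {
  mode <- match.arg(mode)
  if (mode == "unreduced") return(list(dosage = dosage, copies = ploidy))
  k <- if (is.null(n_copies)) ploidy / 2 else n_copies
  if (k != round(k) || k < 1)
    stop("reduced gamete requires an even parental ploidy")
  list(dosage = stats::rhyper(length(dosage), dosage, ploidy - dosage, k),
       copies = as.integer(k))
}

#' Form an interploidy hybrid offspring
#'
#' Combines one gamete from each parent. A reduced gamete from a
#' ploidy-`m` parent carries `m/2` allele copies sampled without
#' replacement from the parent's `m` copies at every site; an unreduced
#' (non-disjunct) gamete carries all `m` copies. Offspring ploidy is the
#' sum of the gamete copy numbers, so e.g. a diploid x tetraploid cross
#' with reduced gametes yields a triploid, while an unreduced diploid
#' gamete yields a tetraploid F1.
#'
#' @param mother,father integer dosage vectors of the two parents.
#' @param mother_ploidy,father_ploidy parental ploidies.
#' @param mother_gamete,father_gamete `"reduced"` or `"unreduced"`.
#' @return List with `dosage` (integer vector) and `ploidy` (integer).
#' @export
form_hybrid <- function(mother, mother_ploidy, father, father_ploidy,
                        mother_gamete = "reduced", father_gamete = "reduced") {
  if (length(mother) != length(father)) stop("parent site counts differ")
  gm <- gamete_dosage(mother, mother_ploidy, mother_gamete)
  gf <- gamete_dosage(father, father_ploidy, father_gamete)
  list(dosage = as.integer(gm$dosage + gf$dosage),
       ploidy = as.integer(gm$copies + gf$copies))
}

#' Clonal replicates of a founder with genotyping error and missingness
#'
#' Each clone copies the founder's dosage vector; with probability
#' `error_rate` per site the dosage is resampled uniformly from the other
#' legal dosages `0..ploidy`, and with probability `missing_rate` the call
#' is set missing. This emulates the residual differences (sequencing
#' error, somatic mutation) seen between true clonemates.
#'
#' @param founder integer dosage vector of the founder.
#' @param ploidy founder ploidy.
#' @param error_rate,missing_rate per-site rates in `[0,1)`.
#' @param n_clones number of clonal replicates to generate.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return A [dosage_matrix()] of the clones (founder not included).
#' @export
clone_with_error <- function(founder, ploidy, error_rate = 0.005,
                             missing_rate = 0.02, n_clones = 1L,
                             seed = NULL) {
  if (error_rate < 0 || error_rate >= 1 || missing_rate < 0 ||
      missing_rate >= 1)
    stop("rates must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  J <- length(founder)
  g <- matrix(rep(as.integer(founder), each = n_clones), nrow = n_clones)
  if (error_rate > 0) {
    hit <- which(matrix(stats::runif(n_clones * J) < error_rate,
                        nrow = n_clones))
    if (length(hit)) {
      cur <- g[hit]
      # uniform over the other legal dosages: shift a draw from 0..ploidy-1
      draw <- floor(stats::runif(length(hit)) * ploidy)
      g[hit] <- as.integer(ifelse(draw >= cur, draw + 1L, draw))
    }
  }
  if (missing_rate > 0)
    g[matrix(stats::runif(n_clones * J) < missing_rate,
             nrow = n_clones)] <- NA_integer_
  dosage_matrix(g, rep(as.integer(ploidy), n_clones))
}

# Parental plastome references and maternally copied haplotypes.
simulate_plastome_refs <- function(len, n_diag) {
  bases <- c("A", "C", "G", "T")
  ref_A <- sample(bases, len, replace = TRUE)
  ref_B <- ref_A
  idx <- sample.int(len, n_diag)
  ref_B[idx] <- vapply(ref_A[idx],
                       function(b) sample(setdiff(bases, b), 1L), "")
  list(A = ref_A, B = ref_B, diagnostic = sort(idx))
}

copy_plastome <- function(ref, error) {
  hap <- ref
  hit <- which(stats::runif(length(ref)) < error)
  if (length(hit))
    hap[hit] <- vapply(ref[hit],
                       function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1L), "")
  hap
}

#' Simulate a full mixed-ploidy cohort
#'
#' Runs the whole generator: parental pools, diploid pool-A and
#' tetraploid pool-B parents, the requested hybrid cytotypes, clonal
#' replicates, and per-sample plastome haplotypes inherited from the
#' maternal parent. Hybrid crosses cycle over the parental individuals:
#'
#' * `triploid_F1` — diploid A mother (reduced, 1 copy) x tetraploid B
#'   father (reduced, 2 copies); plastome A.
#' * `tetraploid_unreduced_F1` — diploid A mother contributing an
#'   unreduced (non-disjunct) gamete x tetraploid B father (reduced);
#'   plastome A.
#' * `diploid_introgressant` — a triploid F1 mother (plastome B)
#'   contributes a single-copy gamete, a diploid A father a reduced
#'   gamete; expected pool-A genome fraction 2/3.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_dataset`: `pools`, `genotypes` (a
#'   [dosage_matrix()] of all samples), `metadata` (sample, taxon,
#'   morphotype, ploidy, clone_group, maternal_pool), `plastome_refs`,
#'   `plastomes` (character matrix samples x positions), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pools <- simulate_parental_pools(config)
  J <- config$n_sites

  ids <- character(0); ploidy <- integer(0); taxon <- character(0)
  morph <- character(0); maternal <- character(0)
  rows <- list()
  add <- function(id, dosage, pl, tax, mo, mat) {
    rows[[length(rows) + 1L]] <<- dosage
    ids <<- c(ids, id); ploidy <<- c(ploidy, pl)
    taxon <<- c(taxon, tax); morph <<- c(morph, mo)
    maternal <<- c(maternal, mat)
  }

  pa <- draw_genotypes(pools, 2L, "A", config$n_parents_A)
  for (i in seq_len(config$n_parents_A))
    add(paste0("A", i), pa$dosage[i, ], 2L, "parent_A", "parental_A", "A")
  pb <- draw_genotypes(pools, 4L, "B", config$n_parents_B)
  for (i in seq_len(config$n_parents_B))
    add(paste0("B", i), pb$dosage[i, ], 4L, "parent_B", "parental_B", "B")

  h_id <- 0L
  for (cyto in names(config$hybrids)) {
    for (k in seq_len(config$hybrids[[cyto]])) {
      h_id <- h_id + 1L
      im <- (h_id - 1L) %% config$n_parents_A + 1L
      ip <- (h_id - 1L) %% config$n_parents_B + 1L
      mA <- pa$dosage[im, ]; fB <- pb$dosage[ip, ]
      if (cyto == "triploid_F1") {
        off <- form_hybrid(mA, 2L, fB, 4L, "reduced", "reduced")
        add(paste0("H", h_id), off$dosage, off$ploidy, "hybrid",
            "triploid_F1", "A")
      } else if (cyto == "tetraploid_unreduced_F1") {
        off <- form_hybrid(mA, 2L, fB, 4L, "unreduced", "reduced")
        add(paste0("H", h_id), off$dosage, off$ploidy, "hybrid",
            "tetraploid_unreduced_F1", "A")
      } else {  # diploid_introgressant
        f1 <- form_hybrid(mA, 2L, fB, 4L, "reduced", "reduced")
        gm <- gamete_dosage(f1$dosage, f1$ploidy, "reduced", n_copies = 1L)
        gf <- gamete_dosage(pa$dosage[(im %% config$n_parents_A) + 1L, ],
                            2L, "reduced")
        add(paste0("H", h_id), as.integer(gm$dosage + gf$dosage), 2L,
            "hybrid", "diploid_introgressant", "B")
      }
    }
  }

  geno <- do.call(rbind, rows)
  rownames(geno) <- ids
  clone_group <- ids
  names(clone_group) <- ids

  if (length(config$clones)) {
    for (fid in names(config$clones)) {
      if (!fid %in% ids) stop("unknown clone founder: ", fid)
      fi <- match(fid, ids)
      cl <- clone_with_error(geno[fi, ], ploidy[fi],
                             config$error_rate, config$missing_rate,
                             n_clones = config$clones[[fid]])
      cn <- paste0(fid, "_c", seq_len(nrow(cl$dosage)))
      geno <- rbind(geno, cl$dosage)
      rownames(geno) <- c(ids, cn)
      ids <- c(ids, cn)
      ploidy <- c(ploidy, cl$ploidy)
      taxon <- c(taxon, rep(taxon[fi], length(cn)))
      morph <- c(morph, rep(morph[fi], length(cn)))
      maternal <- c(maternal, rep(maternal[fi], length(cn)))
      clone_group <- c(clone_group, stats::setNames(rep(fid, length(cn)), cn))
    }
  }

  refs <- simulate_plastome_refs(config$plastome_length,
                                 config$plastome_diag_sites)
  plastomes <- t(vapply(maternal, function(m)
    copy_plastome(refs[[m]], config$plastome_error),
    character(config$plastome_length)))
  rownames(plastomes) <- ids

  meta <- data.frame(sample = ids, taxon = taxon, morphotype = morph,
                     ploidy = ploidy, clone_group = unname(clone_group),
                     maternal_pool = maternal, stringsAsFactors = FALSE)
  variants <- sim_variants(config)
  quality <- sim_genotype_quality(length(ids), nrow(variants))
  structure(list(pools = pools,
                 genotypes = dosage_matrix(geno, ploidy),
                 metadata = meta,
                 variants = variants,
                 gq = quality$gq,
                 dp = quality$dp,
                 plastome_refs = refs,
                 plastomes = plastomes,
                 config = config),
            class = "sim_dataset")
}
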