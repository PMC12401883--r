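#' Shared-heterozygosity index between two individuals
#'
#' Clonemate statistic on diploid-coded genotypes: the number of sites
#' heterozygous in both individuals divided by the larger of the two
#' per-individual heterozygous-site counts. Sites missing in either
#' individual are excluded pairwise. Defined as 0 when neither
#' individual carries a heterozygous site. Clonemates score near 1.
#'
#' @param a,b diploid-coded genotype vectors (`0/1/2`, `NA` missing).
#' @param numerator `"joint"` (default) counts jointly heterozygous
#'   sites; `"union"` is the alternative reading counting sites
#'   heterozygous in at least one individual (kept switchable because the
#'   index is only loosely specified in the literature).
#' @return SH in `[0, 1]`, symmetric in its arguments.
#' @export
shared_heterozygosity <- function(a, b, numerator = c("joint", "union")) {
  if (length(a) != length(b)) stop("genotype vectors differ in length")
  numerator <- match.arg(numerator)
  ok <- !is.na(a) & !is.na(b)
  ha <- a[ok] == 1L
  hb <- b[ok] == 1L
  denom <- max(sum(ha), sum(hb))
  if (denom == 0L) return(0)
  num <- if (numerator == "joint") sum(ha & hb) else sum(ha | hb)
  min(num / denom, 1)
}

# Unbiased (falling-factorial) estimator of a monomial p^a * q^b from
# sample allele counts X (alt), Y (ref), S = X + Y chromosomes:
#   X(X-1)...(X-a+1) * Y(Y-1)...(Y-b+1) / S(S-1)...(S-a-b+1)
ff_monomial <- function(X, Y, a, b) {
  S <- X + Y
  num <- rep(1, length(X))
  for (k in 0:(a - 1)) if (a > 0) num <- num * (X - k)
  if (a == 0) num <- rep(1, length(X))
  den <- rep(1, length(X))
  if (b > 0) for (k in 0:(b - 1)) num <- num * (Y - k)
  for (k in 0:(a + b - 1)) den <- den * (S - k)
  num / den
}

#' Method-of-moments identity-by-descent for one pair
#'
#' Estimates the probabilities Z0, Z1, Z2 that the pair shares 0, 1 or 2
#' alleles identical by descent, from identity-by-state counts corrected
#' by their expectations under the sample allele frequencies (finite-
#' sample falling-factorial corrections). Estimates are truncated to
#' `[0, 1]` and renormalised; the genome-wide IBD proportion is
#' PI_HAT = Z2 + Z1/2.
#'
#' @param a,b diploid-coded genotype vectors.
#' @param alt_count,n_chr per-site alternate-allele counts and chromosome
#'   counts from the full sample at the same sites (used for the
#'   expectation corrections). Sites with minor allele count < 2 are
#'   dropped as uninformative.
#' @param min_sites minimum number of informative sites; below it the
#'   estimate is flagged `low_confidence` (default 100).
#' @return List with `Z0`, `Z1`, `Z2`, `PI_HAT`, `n_sites`,
#'   `low_confidence`.
#' @export
ibd_moments <- function(a, b, alt_count, n_chr, min_sites = 100L) {
  if (length(a) != length(b)) stop("genotype vectors differ in length")
  stopifnot(length(alt_count) == length(a), length(n_chr) == length(a))
  X <- alt_count; Y <- n_chr - alt_count
  ok <- !is.na(a) & !is.na(b) & !is.na(X) & pmin(X, Y) >= 2
  a <- a[ok]; b <- b[ok]; X <- X[ok]; Y <- Y[ok]
  n <- length(a)
  if (n == 0L)
    return(list(Z0 = NA_real_, Z1 = NA_real_, Z2 = NA_real_,
                PI_HAT = NA_real_, n_sites = 0L, low_confidence = TRUE))
  ibs <- 2L - abs(a - b)
  N0 <- sum(ibs == 0L); N1 <- sum(ibs == 1L); N2 <- sum(ibs == 2L)

  # expected per-site IBS probabilities given IBD state, summed over sites
  S00 <- sum(2 * ff_monomial(X, Y, 2, 2))
  S10 <- sum(4 * ff_monomial(X, Y, 3, 1) + 4 * ff_monomial(X, Y, 1, 3))
  S20 <- sum(ff_monomial(X, Y, 4, 0) + ff_monomial(X, Y, 0, 4) +
               4 * ff_monomial(X, Y, 2, 2))
  S11 <- sum(2 * ff_monomial(X, Y, 2, 1) + 2 * ff_monomial(X, Y, 1, 2))
  S21 <- sum(ff_monomial(X, Y, 3, 0) + ff_monomial(X, Y, 0, 3) +
               ff_monomial(X, Y, 2, 1) + ff_monomial(X, Y, 1, 2))

  Z0 <- N0 / S00
  Z1 <- (N1 - Z0 * S10) / S11
  Z2 <- (N2 - Z0 * S20 - Z1 * S21) / n
  z <- pmin(pmax(c(Z0, Z1, Z2), 0), 1)
  z <- z / sum(z)
  pi_hat <- min(max(z[3] + z[2] / 2, 0), 1)
  list(Z0 = z[1], Z1 = z[2], Z2 = z[3], PI_HAT = pi_hat,
       n_sites = n, low_confidence = n < min_sites)
}

#' Pairwise relatedness table for a cohort
#'
#' Computes SH for every sample pair on the full diploid-coded matrix
#' and the method-of-moments IBD components on a (typically LD-pruned)
#' site subset, with allele frequencies estimated from all samples.
#'
#' @param geno_sh diploid-coded matrix (samples x sites) used for SH —
#'   normally the full filtered set.
#' @param geno_ibd diploid-coded matrix used for IBD — normally the
#'   LD-pruned subset. Defaults to `geno_sh`.
#' @param sh_threshold,ibd_threshold clonality flags: SH > 0.90 and
#'   PI_HAT > 0.95 by default.
#' @param min_sites passed to [ibd_moments()].
#' @return data.frame of class `relatedness_table`: one row per pair
#'   with `id1`, `id2`, `n_sites`, `SH`, `Z0`, `Z1`, `Z2`, `PI_HAT`,
#'   `clonal_by_SH`, `clonal_by_IBD`, `low_confidence`.
#' @export
relatedness_table <- function(geno_sh, geno_ibd = geno_sh,
                              sh_threshold = 0.90, ibd_threshold = 0.95,
                              min_sites = 100L) {
  n <- nrow(geno_sh)
  stopifnot(n >= 2L, nrow(geno_ibd) == n)
  ids <- rownames(geno_sh)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  alt_count <- colSums(geno_ibd, na.rm = TRUE)
  n_chr <- 2 * colSums(!is.na(geno_ibd))
  pairs <- utils::combn(n, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sh <- shared_heterozygosity(geno_sh[i, ], geno_sh[j, ])
    ibd <- ibd_moments(geno_ibd[i, ], geno_ibd[j, ], alt_count, n_chr,
                       min_sites = min_sites)
    data.frame(id1 = ids[i], id2 = ids[j], n_sites = ibd$n_sites,
               SH = sh, Z0 = ibd$Z0, Z1 = ibd$Z1, Z2 = ibd$Z2,
               PI_HAT = ibd$PI_HAT,
               clonal_by_SH = !is.na(sh) && sh > sh_threshold,
               clonal_by_IBD = !is.na(ibd$PI_HAT) &&
                 ibd$PI_HAT > ibd_threshold,
               low_confidence = ibd$low_confidence,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("relatedness_table", "data.frame")
  res
}

#' Group samples into clonal lineages
#'
#' Links every pair whose IBD proportion exceeds the clonality threshold
#' and takes connected components of the resulting graph as clone groups
#' (the transitive closure of pairwise clonality).
#'
#' @param rel a [relatedness_table()].
#' @param ibd_threshold PI_HAT cut-off for linking a pair (default 0.95).
#' @param sh_threshold SH cut-off reported alongside (default 0.90).
#' @return data.frame with `sample` and `clone_group` (group label =
#'   lexicographically first member id; singletons form their own group).
#' @export
call_clones <- function(rel, ibd_threshold = 0.95, sh_threshold = 0.90) {
  ids <- sort(unique(c(rel$id1, rel$id2)))
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link <- rel[!is.na(rel$PI_HAT) & rel$PI_HAT > ibd_threshold, , drop = FALSE]
  for (k in seq_len(nrow(link))) {
    ri <- find(match(link$id1[k], ids))
    rj <- find(match(link$id2[k], ids))
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_along(ids), find, integer(1))
  data.frame(sample = ids, clone_group = ids[root],
             stringsAsFactors = FALSE)
}
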