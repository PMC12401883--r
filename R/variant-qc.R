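#' Remove SNPs near indels and non-biallelic records
#'
#' First stage of the hard-filter cascade: drops every SNP lying within
#' `window` bp (inclusive, per contig) of an indel or other variant type,
#' and drops all non-biallelic-SNP records themselves. Input must be
#' sorted by (contig, position).
#'
#' @param sites data.frame with columns `chrom`, `pos`, `type` (`"SNP"`,
#'   `"indel"` or `"other"`), as produced by [read_dosage_vcf()].
#' @param window proximity window in bp (default 20).
#' @return Integer vector of retained row indices into `sites`.
#' @export
proximity_biallelic_filter <- function(sites, window = 20L) {
  ord <- order(sites$chrom, sites$pos)
  if (any(ord != seq_len(nrow(sites))))
    stop("`sites` must be sorted by (contig, position)")
  keep <- which(sites$type == "SNP")
  disturb <- sites[sites$type != "SNP", c("chrom", "pos")]
  if (nrow(disturb) == 0L || length(keep) == 0L) return(keep)
  ok <- vapply(keep, function(i) {
    same <- disturb$chrom == sites$chrom[i]
    !any(abs(disturb$pos[same] - sites$pos[i]) <= window)
  }, logical(1))
  keep[ok]
}

#' Site-level hard filters on variant annotations
#'
#' Applies the GATK-style exclusion criteria: a site fails if any of
#' QD < `min_qd`, FS > `max_fs`, SOR > `max_sor`, MQ < `min_mq`,
#' |MQRankSum| > `ranksum`, DP > `dp_mult` x `mean_depth`, or
#' ReadPosRankSum > `ranksum` holds. Absent (NA) annotations cannot be
#' evaluated and do not trigger failure. Failure reasons are recorded per
#' site.
#'
#' @param sites data.frame with annotation columns `QD`, `FS`, `SOR`,
#'   `MQ`, `MQRankSum`, `DP`, `ReadPosRankSum`.
#' @param mean_depth dataset mean site depth; the depth cutoff is
#'   `dp_mult * mean_depth` (twice the average depth by default).
#' @param min_qd,max_fs,max_sor,min_mq,ranksum,dp_mult filter thresholds.
#' @return List with `retained` (row indices of passing sites) and
#'   `reasons` (character vector, `NA` for passes, otherwise
#'   comma-separated violated criteria).
#' @export
site_hard_filter <- function(sites, mean_depth,
                             min_qd = 10, max_fs = 60, max_sor = 3,
                             min_mq = 40, ranksum = 2.5, dp_mult = 2) {
  if (!is.numeric(mean_depth) || mean_depth <= 0)
    stop("`mean_depth` must be positive")
  chk <- function(x) !is.na(x) & x  # NA annotation never fails
  fails <- cbind(
    QD = chk(sites$QD < min_qd),
    FS = chk(sites$FS > max_fs),
    SOR = chk(sites$SOR > max_sor),
    MQ = chk(sites$MQ < min_mq),
    MQRankSum = chk(abs(sites$MQRankSum) > ranksum),
    DP = chk(sites$DP > dp_mult * mean_depth),
    ReadPosRankSum = chk(sites$ReadPosRankSum > ranksum))
  reasons <- apply(fails, 1, function(f)
    if (any(f)) paste(colnames(fails)[f], collapse = ",") else NA_character_)
  list(retained = which(!apply(fails, 1, any)), reasons = unname(reasons))
}

#' Mask low-confidence genotype calls
#'
#' Sets an individual call to missing when its genotype quality or depth
#' falls below threshold (GQ < `min_gq` OR DP < `min_dp`; either failure
#' masks). Calls with absent GQ/DP are left untouched.
#'
#' @param dosage samples x sites dosage matrix.
#' @param gq,dp matrices of per-call genotype quality and depth,
#'   dimensioned like `dosage`.
#' @param min_gq,min_dp masking thresholds (defaults 30 and 10).
#' @return The dosage matrix with masked entries set to `NA`.
#' @export
genotype_mask <- function(dosage, gq, dp, min_gq = 30, min_dp = 10) {
  stopifnot(all(dim(dosage) == dim(gq)), all(dim(dosage) == dim(dp)))
  bad <- (!is.na(gq) & gq < min_gq) | (!is.na(dp) & dp < min_dp)
  dosage[bad] <- NA_integer_
  dosage
}

#' Diploidized ("non-ploidy") recoding of polyploid calls
#'
#' Collapses each dosage to a diploid code: 0 stays homozygous-reference
#' (0), full dosage (`== ploidy`) becomes homozygous-alternate (2), and
#' any intermediate dosage becomes heterozygous (1). Missing stays
#' missing. Idempotent on already-diploid input.
#'
#' @param dosage samples x sites dosage matrix.
#' @param ploidy per-sample ploidy vector.
#' @return Integer matrix with entries in `{0, 1, 2, NA}`.
#' @export
diploidize <- function(dosage, ploidy) {
  ploidy <- as.integer(ploidy)
  if (length(ploidy) == 1L) ploidy <- rep(ploidy, nrow(dosage))
  stopifnot(length(ploidy) == nrow(dosage))
  if (any(sweep(dosage, 1L, ploidy, ">"), na.rm = TRUE))
    stop("dosage exceeds ploidy")
  out <- matrix(1L, nrow(dosage), ncol(dosage),
                dimnames = dimnames(dosage))
  out[dosage == 0L] <- 0L
  out[sweep(dosage, 1L, ploidy, "==")] <- 2L
  out[is.na(dosage)] <- NA_integer_
  out
}

#' Run the full SNP hard-filter cascade
#'
#' Chains the three stages in the order proximity/biallelic filter ->
#' site hard filters -> genotype-level masking, and reports the retained
#' count after each stage.
#'
#' @param vcf a `vcf_data` object from [read_dosage_vcf()].
#' @param window proximity window in bp.
#' @param mean_depth dataset mean depth; defaults to the mean of the site
#'   DP annotations.
#' @param min_gq,min_dp genotype-masking thresholds.
#' @param ... further thresholds passed to [site_hard_filter()].
#' @return List of class `filter_result`: `dosage` (masked, filtered
#'   samples x sites matrix), `sites` (retained site table), `ploidy`,
#'   `report` (a `filter_report` data.frame of per-stage retained
#'   counts) and `reasons` (per-site failure reasons for the site-filter
#'   stage, aligned to the stage-1 survivors).
#' @export
filter_variants <- function(vcf, window = 20L, mean_depth = NULL,
                            min_gq = 30, min_dp = 10, ...) {
  stopifnot(inherits(vcf, "vcf_data"))
  n_input <- nrow(vcf$sites)
  keep1 <- proximity_biallelic_filter(vcf$sites, window)
  sites1 <- vcf$sites[keep1, , drop = FALSE]
  if (is.null(mean_depth)) mean_depth <- mean(sites1$DP, na.rm = TRUE)
  hf <- site_hard_filter(sites1, mean_depth, ...)
  keep2 <- keep1[hf$retained]
  dosage <- genotype_mask(vcf$dosage[, keep2, drop = FALSE],
                          vcf$gq[, keep2, drop = FALSE],
                          vcf$dp[, keep2, drop = FALSE],
                          min_gq = min_gq, min_dp = min_dp)
  report <- data.frame(
    stage = c("input", "proximity_biallelic", "site_filters",
              "genotype_mask"),
    retained_sites = c(n_input, length(keep1), length(keep2),
                       length(keep2)),
    masked_calls = c(0L, 0L, 0L, sum(is.na(dosage)) -
                       sum(is.na(vcf$dosage[, keep2, drop = FALSE]))))
  stopifnot(!is.unsorted(rev(report$retained_sites)))
  structure(list(dosage = dosage,
                 sites = vcf$sites[keep2, , drop = FALSE],
                 ploidy = vcf$ploidy,
                 report = report,
                 reasons = hf$reasons),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("SNP hard-filter cascade\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
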