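#' Sliding-window linkage-disequilibrium pruning
#'
#' Greedy within-window pruning of correlated sites, mirroring the
#' `--indep-pairwise <window> <step> <r2>` semantics: within each window
#' of `window` consecutive sites (sliding by `step` sites), the squared
#' Pearson correlation of dosages is computed for every pair of
#' still-retained sites, and when r-squared exceeds the threshold the
#' later site of the pair is dropped. The retained set is deterministic
#' for a fixed input column order and invariant to adding a constant to
#' a site's dosages.
#'
#' @param geno samples x sites genotype matrix (diploid- or
#'   dosage-coded; `NA` allowed, correlations use pairwise-complete
#'   observations).
#' @param window window size in sites (default 50).
#' @param step window slide in sites (default 5).
#' @param r2_threshold squared-correlation threshold (default 0.7).
#' @return Integer vector of retained column indices.
#' @export
ld_prune <- function(geno, window = 50L, step = 5L, r2_threshold = 0.7) {
  if (window < step) stop("`window` must be >= `step`")
  J <- ncol(geno)
  keep <- rep(TRUE, J)
  if (J < 2L) return(which(keep))
  starts <- seq(1L, max(1L, J - 1L), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1L, J)
    idx <- idx[keep[idx]]
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(
      stats::cor(geno[, idx, drop = FALSE],
                 use = "pairwise.complete.obs"))^2
    r2[!is.finite(r2)] <- 0
    # a site is dropped iff it exceeds the threshold against an earlier
    # still-retained site in this window (equivalent to ordered pairwise
    # greedy elimination)
    live <- rep(TRUE, length(idx))
    for (jj in 2:length(idx)) {
      if (any(r2[which(live[seq_len(jj - 1L)]), jj] > r2_threshold)) {
        live[jj] <- FALSE
        keep[idx[jj]] <- FALSE
      }
    }
  }
  which(keep)
}

#' Genotype principal component analysis
#'
#' PCA of the diploid-coded genotype matrix with allele-frequency
#' scaling: missing entries are mean-imputed per site, each site is
#' centred by its mean dosage and scaled by the binomial standard
#' deviation `sqrt(p(1-p))` at the estimated allele frequency, and the
#' eigendecomposition of the resulting sample covariance gives the
#' coordinates. Monomorphic sites carry no information and are dropped.
#'
#' @param geno diploid-coded matrix (samples x sites), at least 3 samples.
#' @return List of class `genotype_pca`: `scores` (samples x axes),
#'   `var_explained` (percent per axis, non-increasing, summing to
#'   <= 100), `n_sites` used.
#' @export
pca_genotypes <- function(geno) {
  if (nrow(geno) < 3L) stop("need at least 3 samples")
  mu <- colMeans(geno, na.rm = TRUE)
  if (anyNA(mu)) stop("all-missing site; filter upstream")
  G <- geno
  na <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na)) G[na] <- mu[na[, 2]]
  p <- mu / 2
  poly <- p > 0 & p < 1
  G <- G[, poly, drop = FALSE]
  Z <- sweep(G, 2, mu[poly], "-")
  Z <- sweep(Z, 2, sqrt(p[poly] * (1 - p[poly])), "/")
  sv <- svd(Z)
  ev <- sv$d^2
  k <- min(nrow(G) - 1L, length(ev))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(geno),
                           paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 var_explained = 100 * ev[seq_len(k)] / sum(ev),
                 n_sites = ncol(G)),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("Genotype PCA on %d polymorphic sites\n", x$n_sites))
  ve <- x$var_explained[seq_len(min(5, length(x$var_explained)))]
  cat("  variance explained (%):",
      paste(sprintf("%.1f", ve), collapse = " "), "\n")
  invisible(x)
}
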