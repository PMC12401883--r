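#' Dosage-aware admixture model for mixed-ploidy cohorts
#'
#' Fits a Bayesian admixture model in which the alternate-allele dosage
#' of sample i at site j is Binomial(m_i, sum_k q_ik f_kj): m_i is the
#' sample's ploidy, q_i the sample's ancestry proportions over K clusters
#' (Dirichlet(1) prior) and f_k the cluster allele frequencies
#' (Beta(1,1) prior). Inference is by Gibbs sampling with per-copy
#' ancestry augmentation, run as several independent chains whose cluster
#' labels are aligned afterwards by matching cluster frequency vectors.
#' Missing dosages are marginalised (skipped in the likelihood), not
#' imputed.
#'
#' Model fit is summarised by the deviance information criterion
#' (DIC = mean deviance + p_D, with p_D = mean deviance minus the
#' deviance at the posterior-mean parameters) and the log-pointwise
#' predictive density (lppd) over retained draws. Convergence is
#' monitored by split-R-hat on the ancestry proportions; values above
#' 1.1 trigger a warning but the fit is still returned.
#'
#' @param geno samples x sites integer dosage matrix (`NA` missing).
#' @param ploidy per-sample ploidy vector.
#' @param K number of ancestry clusters (>= 1).
#' @param chains number of MCMC chains (default 3).
#' @param iter iterations per chain (default 2000).
#' @param burn fraction of iterations discarded as burn-in (default 0.5).
#' @param thin keep every `thin`-th post-burn-in draw (default 5).
#' @param seed integer seed for the sampler.
#' @return Object of class `ancestry_fit`: posterior means `q`
#'   (samples x K, rows on the simplex) and `f` (K x sites), `K`, `DIC`,
#'   `lppd`, `deviance` (retained draws, all chains), `rhat` (max
#'   split-R-hat over q entries), `n_draws`, `call`.
#' @seealso [select_K()], [coef.ancestry_fit()], [plot.ancestry_fit()]
#' @export
admixture_fit <- function(geno, ploidy, K, chains = 3L, iter = 2000L,
                          burn = 0.5, thin = 5L, seed = 1L) {
  stopifnot(K >= 1L, iter >= 10L, chains >= 1L)
  ploidy <- as.integer(ploidy)
  if (length(ploidy) == 1L) ploidy <- rep(ploidy, nrow(geno))
  stopifnot(length(ploidy) == nrow(geno))
  n <- nrow(geno); J <- ncol(geno)
  obs <- !is.na(geno)
  g <- geno; g[!obs] <- 0L
  m <- matrix(ploidy, n, J)
  m[!obs] <- 0L
  storage.mode(g) <- "double"; storage.mode(m) <- "double"

  set.seed(seed)
  res <- lapply(seq_len(chains), function(ch)
    admix_chain(g, m, obs, K, iter, burn, thin))

  # align cluster labels across chains to chain 1 by matching the
  # posterior-mean frequency vectors
  ref_f <- res[[1]]$f_mean
  for (ch in seq_along(res)[-1]) {
    perm <- best_permutation(res[[ch]]$f_mean, ref_f)
    res[[ch]]$f_mean <- res[[ch]]$f_mean[perm, , drop = FALSE]
    res[[ch]]$q_mean <- res[[ch]]$q_mean[, perm, drop = FALSE]
    res[[ch]]$q_draws <- res[[ch]]$q_draws[, , perm, drop = FALSE]
  }

  nd <- sum(vapply(res, function(r) r$n_draws, integer(1)))
  q_mean <- Reduce(`+`, lapply(res, function(r) r$q_mean * r$n_draws)) / nd
  f_mean <- Reduce(`+`, lapply(res, function(r) r$f_mean * r$n_draws)) / nd
  p_acc <- Reduce(`+`, lapply(res, function(r) r$p_acc))
  lppd <- sum(log(p_acc[obs] / nd))
  dev_draws <- unlist(lapply(res, function(r) r$deviance))
  dbar <- mean(dev_draws)
  dhat <- admix_deviance(g, m, obs, q_mean, f_mean)
  dic <- dbar + (dbar - dhat)

  rhat <- if (chains >= 2L && K >= 2L)
    max(apply_rhat(lapply(res, function(r) r$q_draws))) else NA_real_
  if (is.finite(rhat) && rhat > 1.1)
    warning(sprintf("split-R-hat on q is %.3f (> 1.1): chains may not have converged",
                    rhat))

  rownames(q_mean) <- rownames(geno)
  colnames(q_mean) <- paste0("cluster", seq_len(K))
  structure(list(q = q_mean, f = f_mean, K = as.integer(K), DIC = dic,
                 lppd = lppd, p_D = dbar - dhat, deviance = dev_draws,
                 rhat = rhat, n_draws = nd, n_samples = n, n_sites = J,
                 ploidy = ploidy, call = match.call()),
            class = "ancestry_fit")
}

admix_deviance <- function(g, m, obs, q, f) {
  theta <- pmin(pmax(q %*% f, 1e-9), 1 - 1e-9)
  ll <- stats::dbinom(g, m, theta, log = TRUE)
  -2 * sum(ll[obs])
}

admix_chain <- function(g, m, obs, K, iter, burn, thin) {
  n <- nrow(g); J <- ncol(g)
  q <- matrix(stats::rgamma(n * K, 1), n, K)
  q <- q / rowSums(q)
  f <- matrix(stats::runif(K * J, 0.05, 0.95), K, J)
  keep_from <- floor(iter * burn) + 1L
  keep_iters <- seq(keep_from, iter)
  keep_iters <- keep_iters[(keep_iters - keep_from) %% thin == 0L]
  nk <- length(keep_iters)
  q_draws <- array(NA_real_, c(nk, n, K))
  q_acc <- matrix(0, n, K); f_acc <- matrix(0, K, J)
  p_acc <- matrix(0, n, J); dev <- numeric(nk)
  ki <- 0L
  ref <- m - g

  for (it in seq_len(iter)) {
    # weights for alt and ref copies: W_k = q_ik * f_kj (resp. 1 - f)
    Wa <- lapply(seq_len(K), function(k) tcrossprod(q[, k], f[k, ]))
    Wr <- lapply(seq_len(K), function(k) tcrossprod(q[, k], 1 - f[k, ]))
    A <- split_counts(g, Wa, K)
    R <- split_counts(ref, Wr, K)
    for (k in seq_len(K))
      f[k, ] <- pmin(pmax(stats::rbeta(J, 1 + colSums(A[[k]]),
                                       1 + colSums(R[[k]])),
                          1e-6), 1 - 1e-6)
    cnt <- vapply(seq_len(K),
                  function(k) rowSums(A[[k]]) + rowSums(R[[k]]),
                  numeric(n))
    q <- matrix(stats::rgamma(n * K, 1 + cnt), n, K)
    q <- q / rowSums(q)

    if (it %in% keep_iters) {
      ki <- ki + 1L
      theta <- pmin(pmax(q %*% f, 1e-9), 1 - 1e-9)
      ll <- stats::dbinom(g, m, theta, log = TRUE)
      dev[ki] <- -2 * sum(ll[obs])
      p_acc <- p_acc + exp(ll)
      q_acc <- q_acc + q; f_acc <- f_acc + f
      q_draws[ki, , ] <- q
    }
  }
  list(q_mean = q_acc / nk, f_mean = f_acc / nk, p_acc = p_acc,
       deviance = dev, q_draws = q_draws, n_draws = nk)
}

# distribute integer counts `tot` (n x J) over K categories with weights
# W (list of n x J matrices) via sequential binomial splits
split_counts <- function(tot, W, K) {
  n <- nrow(tot); J <- ncol(tot)
  out <- vector("list", K)
  if (K == 1L) { out[[1]] <- tot; return(out) }
  rem <- tot
  remw <- Reduce(`+`, W)
  for (k in seq_len(K - 1L)) {
    p <- W[[k]] / remw
    p[!is.finite(p)] <- 0
    out[[k]] <- matrix(stats::rbinom(n * J, rem, pmin(pmax(p, 0), 1)),
                       n, J)
    rem <- rem - out[[k]]
    remw <- remw - W[[k]]
  }
  out[[K]] <- rem
  out
}

best_permutation <- function(f, ref) {
  K <- nrow(f)
  perms <- all_permutations(K)
  cost <- vapply(perms, function(p) sum((f[p, , drop = FALSE] - ref)^2),
                 numeric(1))
  perms[[which.min(cost)]]
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(K))
      out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
  out
}

# split-R-hat over chains for each (sample, cluster) entry of q
apply_rhat <- function(q_draw_list) {
  n <- dim(q_draw_list[[1]])[2]; K <- dim(q_draw_list[[1]])[3]
  vapply(seq_len(n * K), function(idx) {
    i <- (idx - 1L) %% n + 1L
    k <- (idx - 1L) %/% n + 1L
    halves <- list()
    for (ch in q_draw_list) {
      x <- ch[, i, k]
      h <- length(x) %/% 2L
      halves <- c(halves, list(x[seq_len(h)], x[h + seq_len(h)]))
    }
    split_rhat(halves)
  }, numeric(1))
}

split_rhat <- function(halves) {
  m <- length(halves); nn <- length(halves[[1]])
  if (nn < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W < 1e-12) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Select the number of ancestry clusters by DIC
#'
#' Given admixture fits over a range of K, returns the K minimising the
#' deviance information criterion, with ties broken toward the smaller
#' K; the log-pointwise predictive density is reported alongside.
#'
#' @param fits list of [admixture_fit()] results (at least 2).
#' @return List of class `k_selection`: `K` (selected), `table`
#'   (data.frame of K, DIC, lppd, p_D ordered by K).
#' @export
select_K <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L)
    stop("need fits for at least 2 values of K")
  stopifnot(all(vapply(fits, inherits, logical(1), "ancestry_fit")))
  tab <- data.frame(K = vapply(fits, `[[`, integer(1), "K"),
                    DIC = vapply(fits, `[[`, numeric(1), "DIC"),
                    lppd = vapply(fits, `[[`, numeric(1), "lppd"),
                    p_D = vapply(fits, `[[`, numeric(1), "p_D"))
  tab <- tab[order(tab$K), , drop = FALSE]
  best <- tab$K[which.min(tab$DIC)]  # which.min takes the first minimum
  structure(list(K = best, table = tab), class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Cluster-number selection by DIC\n")
  print(x$table, row.names = FALSE)
  cat("selected K =", x$K, "\n")
  invisible(x)
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("Mixed-ploidy admixture fit: K = %d, %d samples, %d sites\n",
              x$K, x$n_samples, x$n_sites))
  cat(sprintf("  DIC = %.1f  lppd = %.1f  p_D = %.1f  draws = %d\n",
              x$DIC, x$lppd, x$p_D, x$n_draws))
  if (is.finite(x$rhat))
    cat(sprintf("  max split-R-hat(q) = %.3f\n", x$rhat))
  invisible(x)
}

#' @export
summary.ancestry_fit <- function(object, ...) {
  print(object)
  cat("\nPosterior-mean ancestry proportions:\n")
  print(round(object$q, 3))
  invisible(object)
}

#' Posterior-mean ancestry proportions
#' @param object an `ancestry_fit`.
#' @param ... unused.
#' @return Samples x K matrix of admixture proportions (rows sum to 1).
#' @export
coef.ancestry_fit <- function(object, ...) object$q

#' Admixture bar plot
#'
#' Stacked per-sample bars of the posterior-mean ancestry proportions,
#' the standard way of displaying an admixture fit.
#'
#' @param x an `ancestry_fit`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ancestry_fit <- function(x, ...) {
  graphics::barplot(t(x$q), col = grDevices::hcl.colors(x$K, "Dark 3"),
                    border = NA, las = 2,
                    ylab = "ancestry proportion", ...)
  invisible(x)
}
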