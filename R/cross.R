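#' Specify an interploidy cross
#'
#' Describes the parents of a (possibly interploidy) cross: ploidies,
#' gamete modes and the base chromosome number x. A reduced gamete from
#' a ploidy-m parent carries m/2 chromosome sets (so m must be even); an
#' unreduced (non-disjunct) gamete carries all m sets.
#'
#' @param maternal_ploidy,paternal_ploidy parental ploidies (integers).
#' @param maternal_gamete,paternal_gamete `"reduced"` or `"unreduced"`.
#' @param x base (monoploid) chromosome number, default 17.
#' @param maternal_taxon,paternal_taxon optional taxon labels.
#' @return List of class `cross_spec`.
#' @export
cross_spec <- function(maternal_ploidy, paternal_ploidy,
                       maternal_gamete = "reduced",
                       paternal_gamete = "reduced",
                       x = 17L,
                       maternal_taxon = "maternal",
                       paternal_taxon = "paternal") {
  maternal_gamete <- match.arg(maternal_gamete, c("reduced", "unreduced"))
  paternal_gamete <- match.arg(paternal_gamete, c("reduced", "unreduced"))
  x <- as.integer(x)
  if (x < 1L) stop("`x` must be >= 1")
  for (side in list(c(maternal_ploidy, maternal_gamete),
                    c(paternal_ploidy, paternal_gamete)))
    if (side[2] == "reduced" && as.integer(side[1]) %% 2L != 0L)
      stop("a reduced gamete requires an even parental ploidy")
  structure(list(maternal_ploidy = as.integer(maternal_ploidy),
                 paternal_ploidy = as.integer(paternal_ploidy),
                 maternal_gamete = maternal_gamete,
                 paternal_gamete = paternal_gamete,
                 x = x,
                 maternal_taxon = maternal_taxon,
                 paternal_taxon = paternal_taxon),
            class = "cross_spec")
}

gamete_sets <- function(ploidy, mode) {
  if (mode == "unreduced") ploidy else ploidy %/% 2L
}

#' Predict the offspring cytotype of a cross
#'
#' Gamete chromosome number is x*m/2 for a reduced gamete and x*m for an
#' unreduced gamete; the offspring somatic number 2n is their sum and the
#' offspring ploidy is 2n / x. For example a diploid x tetraploid cross
#' with reduced gametes gives 2n = 3x = 51 (a triploid at x = 17), while
#' an unreduced diploid gamete gives 2n = 4x = 68 (a tetraploid).
#'
#' @param cross a [cross_spec()].
#' @return List with `ploidy`, `two_n` (somatic chromosome number),
#'   `cytotype` label, and per-parent gamete chromosome numbers
#'   `n_maternal`, `n_paternal`.
#' @export
predict_offspring <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  sm <- gamete_sets(cross$maternal_ploidy, cross$maternal_gamete)
  sp <- gamete_sets(cross$paternal_ploidy, cross$paternal_gamete)
  pl <- sm + sp
  lab <- if (pl <= length(PLOIDY_LABELS)) tolower(PLOIDY_LABELS[pl])
         else paste0(pl, "x")
  list(ploidy = as.integer(pl),
       two_n = as.integer(cross$x * pl),
       cytotype = lab,
       n_maternal = as.integer(cross$x * sm),
       n_paternal = as.integer(cross$x * sp))
}

#' Expected parental genome fractions of the offspring
#'
#' Each parent's expected share of the offspring genome is its gamete
#' copy number divided by the offspring ploidy: a triploid F1 of a
#' diploid and a tetraploid carries (1/3, 2/3), a tetraploid F1 formed
#' through an unreduced diploid gamete carries (1/2, 1/2). Fractions sum
#' to 1.
#'
#' @param cross a [cross_spec()].
#' @return Named numeric vector `c(maternal = ..., paternal = ...)`.
#' @export
expected_ancestry <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  sm <- gamete_sets(cross$maternal_ploidy, cross$maternal_gamete)
  sp <- gamete_sets(cross$paternal_ploidy, cross$paternal_gamete)
  c(maternal = sm / (sm + sp), paternal = sp / (sm + sp))
}

#' Compare fitted ancestry proportions with a cross expectation
#'
#' Flags samples whose fitted admixture fractions deviate from the
#' cross's expected parental genome fractions by more than `tolerance`.
#' The mapping from ancestry clusters to parents must be resolvable:
#' either `q` has columns named `maternal`/`paternal` or an explicit
#' `cluster_map` is supplied.
#'
#' @param q samples x 2 matrix of fitted ancestry proportions (e.g.
#'   `coef()` of an [admixture_fit()] at K = 2).
#' @param cross a [cross_spec()].
#' @param tolerance maximum absolute deviation (default 0.10).
#' @param cluster_map length-2 vector giving the columns of `q` holding
#'   the maternal and paternal cluster, as `c(maternal = i, paternal = j)`.
#' @return data.frame with `sample`, `q_maternal`, `q_paternal`,
#'   `expected_maternal`, `deviation` (max abs), `concordant`.
#' @export
compare_ancestry <- function(q, cross, tolerance = 0.10,
                             cluster_map = NULL) {
  stopifnot(inherits(cross, "cross_spec"))
  q <- as.matrix(q)
  if (ncol(q) != 2L)
    stop("`q` must have exactly 2 cluster columns")
  if (is.null(cluster_map)) {
    if (!all(c("maternal", "paternal") %in% colnames(q)))
      stop("cluster-to-parent mapping unresolvable: name the columns of ",
           "`q` 'maternal'/'paternal' or supply `cluster_map`")
    cluster_map <- c(maternal = match("maternal", colnames(q)),
                     paternal = match("paternal", colnames(q)))
  }
  exp_frac <- expected_ancestry(cross)
  qm <- q[, cluster_map[["maternal"]]]
  qp <- q[, cluster_map[["paternal"]]]
  dev <- pmax(abs(qm - exp_frac[["maternal"]]),
              abs(qp - exp_frac[["paternal"]]))
  ids <- rownames(q)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(q)))
  data.frame(sample = ids, q_maternal = qm, q_paternal = qp,
             expected_maternal = exp_frac[["maternal"]],
             deviation = dev, concordant = dev <= tolerance,
             row.names = NULL, stringsAsFactors = FALSE)
}
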