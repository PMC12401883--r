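#' Assign the maternal parent from a plastome haplotype
#'
#' Plastomes are uniparentally (maternally) inherited, so the parental
#' reference haplotype nearest to a sample's plastome identifies the
#' maternal species. Distance is the Hamming count of mismatching
#' aligned positions, skipping columns where either sequence has a gap
#' (`-`) or an ambiguous base (`N`). The sample is assigned to the
#' unique nearest reference provided the minimum distance is below
#' `max_distance`; ties or over-ceiling minima yield `"unassigned"`.
#'
#' @param haplotype character vector (or single string) of the sample's
#'   aligned plastome haplotype.
#' @param references named list of aligned parental reference
#'   haplotypes, same length as `haplotype`.
#' @param max_distance assignment ceiling; default 10% of the compared
#'   columns.
#' @return List of class `plastome_assignment`: `distances` (named),
#'   `maternal` (reference name or `"unassigned"`).
#' @export
assign_maternal <- function(haplotype, references, max_distance = NULL) {
  hap <- split_seq(haplotype)
  refs <- lapply(references, split_seq)
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("`references` must be named")
  if (any(lengths(refs) != length(hap)))
    stop("haplotype and references differ in aligned length")
  d <- vapply(refs, function(r) {
    ok <- !(hap %in% c("-", "N")) & !(r %in% c("-", "N"))
    sum(hap[ok] != r[ok])
  }, numeric(1))
  if (is.null(max_distance)) max_distance <- 0.1 * length(hap)
  ranked <- sort(d)
  maternal <- if (ranked[1] < max_distance &&
                  (length(ranked) == 1L || ranked[1] < ranked[2]))
    names(ranked)[1] else "unassigned"
  structure(list(distances = d, maternal = maternal),
            class = "plastome_assignment")
}

split_seq <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L)
    x <- strsplit(x, "")[[1]]
  toupper(x)
}

#' Maternal assignment for a cohort of plastomes
#'
#' @param haplotypes named list (or character matrix, samples in rows)
#'   of aligned plastome haplotypes.
#' @param references named list of parental reference haplotypes.
#' @param max_distance passed to [assign_maternal()].
#' @return data.frame with `sample`, one distance column per reference,
#'   and `maternal`.
#' @export
plastome_assignments <- function(haplotypes, references,
                                 max_distance = NULL) {
  if (is.matrix(haplotypes))
    haplotypes <- stats::setNames(
      lapply(seq_len(nrow(haplotypes)), function(i) haplotypes[i, ]),
      rownames(haplotypes))
  out <- lapply(names(haplotypes), function(id) {
    a <- assign_maternal(haplotypes[[id]], references, max_distance)
    cbind(data.frame(sample = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(a$distances)),
          data.frame(maternal = a$maternal, stringsAsFactors = FALSE))
  })
  do.call(rbind, out)
}

#' Map admixture clusters to parental pools
#'
#' Resolves which ancestry cluster corresponds to which parental
#' species by majority assignment of known parental samples.
#'
#' @param fit an [admixture_fit()] with K = 2.
#' @param parent_A_ids,parent_B_ids sample ids of known pool-A and
#'   pool-B parents (row names of `coef(fit)`).
#' @return Integer vector `c(A = column of pool-A cluster, B = ...)`.
#' @export
map_clusters_to_parents <- function(fit, parent_A_ids, parent_B_ids) {
  stopifnot(inherits(fit, "ancestry_fit"), fit$K == 2L)
  q <- fit$q
  a_col <- which.max(colMeans(q[parent_A_ids, , drop = FALSE]))
  b_col <- which.max(colMeans(q[parent_B_ids, , drop = FALSE]))
  if (a_col == b_col)
    stop("cluster-to-parent mapping unresolvable: both parental pools ",
         "load on the same cluster")
  c(A = unname(a_col), B = unname(b_col))
}

#' Integrated per-sample morphotype report
#'
#' Joins the evidence lines — ploidy call, ancestry fractions, clone
#' group and plastome-based maternal parent — into one row per sample
#' and adds a consistency verdict. The verdict combines cytotype and
#' pool-A genome fraction: a tetraploid with q_A near 1/2 is an
#' unreduced-gamete F1 ("morphotype-A-like"), a triploid with q_A near
#' 1/3 a reduced-gamete F1, a diploid with intermediate q_A an
#' introgressant, and diploids/tetraploids loading fully on one pool are
#' parental-like. Missing evidence is reported as `NA`, never
#' fabricated; the report is a pure join, so identical inputs yield
#' identical output.
#'
#' @param ploidy data.frame `sample`, `ploidy`.
#' @param ancestry data.frame `sample`, `q_A` (pool-A fraction); or
#'   `NULL`.
#' @param clones data.frame `sample`, `clone_group` from
#'   [call_clones()]; or `NULL`.
#' @param plastome data.frame `sample`, `maternal` from
#'   [plastome_assignments()]; or `NULL`.
#' @param tolerance half-width of the expected-fraction bands
#'   (default 0.10).
#' @return data.frame, one row per sample: `sample`, `ploidy`, `q_A`,
#'   `clone_group`, `clonal` (group has > 1 member), `maternal`,
#'   `verdict`.
#' @export
morphotype_report <- function(ploidy, ancestry = NULL, clones = NULL,
                              plastome = NULL, tolerance = 0.10) {
  rep_df <- data.frame(sample = ploidy$sample, ploidy = ploidy$ploidy,
                       stringsAsFactors = FALSE)
  merge_in <- function(df, cols) {
    if (is.null(df)) {
      for (cl in cols) rep_df[[cl]] <<- NA
    } else {
      rep_df <<- merge(rep_df, df[, c("sample", cols), drop = FALSE],
                       by = "sample", all.x = TRUE, sort = FALSE)
    }
  }
  merge_in(ancestry, "q_A")
  merge_in(clones, "clone_group")
  merge_in(plastome, "maternal")
  grp_n <- table(rep_df$clone_group)
  rep_df$clonal <- ifelse(is.na(rep_df$clone_group), NA,
                          grp_n[rep_df$clone_group] > 1L)
  rep_df$verdict <- mapply(function(pl, qa) {
    if (is.na(pl) || is.na(qa)) return("insufficient evidence")
    near <- function(x) abs(qa - x) <= tolerance
    if (pl == 4L && near(0.5)) "tetraploid F1 (unreduced gamete)"
    else if (pl == 3L && near(1 / 3)) "triploid F1"
    else if (pl == 2L && qa >= 1 - tolerance) "parental A-like diploid"
    else if (pl == 2L && qa <= tolerance) "parental B-like diploid"
    else if (pl == 4L && (qa >= 1 - tolerance || qa <= tolerance))
      "parental-like tetraploid"
    else if (pl == 2L) "diploid introgressant"
    else "unclassified"
  }, rep_df$ploidy, rep_df$q_A)
  rep_df[match(ploidy$sample, rep_df$sample), , drop = FALSE]
}
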