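#' Dosage matrix container
#'
#' A light container for biallelic SNP genotypes coded as alternate-allele
#' dosages. Rows are samples, columns are sites; entries are integers in
#' `0..ploidy[i]` or `NA` for missing calls. Ploidy may differ between
#' samples (mixed-ploidy cohorts), so the per-sample ploidy vector travels
#' with the matrix.
#'
#' @param dosage integer matrix, samples x sites; `NA` = missing call.
#' @param ploidy integer vector, one entry per sample (row).
#' @param sites optional data.frame of per-site records (contig, pos, ...).
#' @return An object of class `dosage_matrix`: a list with elements
#'   `dosage`, `ploidy` and `sites`.
#' @examples
#' dm <- dosage_matrix(matrix(c(0L, 2L, 1L, 4L), 2, 2,
#'                            dimnames = list(c("a", "b"), NULL)),
#'                     ploidy = c(2L, 4L))
#' dim(dm)
#' @export
dosage_matrix <- function(dosage, ploidy, sites = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  ploidy <- as.integer(ploidy)
  if (length(ploidy) == 1L) ploidy <- rep(ploidy, nrow(dosage))
  if (length(ploidy) != nrow(dosage))
    stop("`ploidy` must have one entry per sample (row)")
  bad <- sweep(dosage, 1L, ploidy, ">")
  if (any(bad, na.rm = TRUE))
    stop("dosage exceeds sample ploidy")
  if (any(dosage < 0L, na.rm = TRUE))
    stop("negative dosage")
  if (!is.null(sites) && nrow(sites) != ncol(dosage))
    stop("`sites` must have one row per site (column)")
  structure(list(dosage = dosage, ploidy = ploidy, sites = sites),
            class = "dosage_matrix")
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosage)

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix: %d samples x %d sites>\n",
              nrow(x$dosage), ncol(x$dosage)))
  tab <- table(factor(x$ploidy, levels = sort(unique(x$ploidy))))
  cat("  ploidy:", paste(sprintf("%sx:%d", names(tab), tab), collapse = " "),
      "\n")
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Bind dosage matrices by sample
#'
#' Row-binds two or more [dosage_matrix()] objects that describe the same
#' sites, concatenating their ploidy vectors.
#'
#' @param ... `dosage_matrix` objects with equal site count.
#' @return A single `dosage_matrix`.
#' @export
rbind_dosage <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L)
  nc <- vapply(xs, function(x) ncol(x$dosage), integer(1))
  if (length(unique(nc)) != 1L) stop("site counts differ")
  dosage_matrix(do.call(rbind, lapply(xs, `[[`, "dosage")),
                unlist(lapply(xs, `[[`, "ploidy")),
                sites = xs[[1L]]$sites)
}
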