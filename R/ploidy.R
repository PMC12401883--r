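PLOIDY_LABELS <- c("Haploid", "Diploid", "Triploid", "Tetraploid",
                   "Pentaploid", "Hexaploid", "Heptaploid", "Octoploid")

#' Classify ploidy from a flow-cytometry 2C value
#'
#' Divides the 2C DNA amount (picograms) by the monoploid genome size
#' 1Cx and rounds to the nearest integer. The call is scale-invariant
#' (only the ratio matters). A ratio farther than `band` from every
#' integer is flagged ambiguous; with the default `band = 0.5` only
#' exact half-integer ties are ambiguous.
#'
#' @param two_c 2C value(s) in pg (vectorised).
#' @param one_cx calibration monoploid genome size in pg (e.g. half the
#'   mean 2C of known diploid reference accessions; see
#'   [calibrate_1cx()]).
#' @param band half-width of the acceptance band around integer ratios.
#' @return data.frame with `two_c`, `ratio`, `ploidy` (integer, >= 1),
#'   `label` (e.g. "Tetraploid"), `ambiguous`.
#' @export
classify_ploidy <- function(two_c, one_cx, band = 0.5) {
  if (any(two_c <= 0) || one_cx <= 0)
    stop("2C and 1Cx values must be positive")
  ratio <- two_c / one_cx
  pl <- pmax(1L, as.integer(round(ratio)))
  amb <- abs(ratio - round(ratio)) >= band - 1e-12
  lab <- ifelse(pl <= length(PLOIDY_LABELS), PLOIDY_LABELS[pl],
                paste0(pl, "x"))
  data.frame(two_c = two_c, ratio = ratio, ploidy = pl, label = lab,
             ambiguous = amb, stringsAsFactors = FALSE)
}

#' Calibrate the monoploid genome size from diploid references
#'
#' 1Cx is half the mean 2C value of accessions known (e.g. from
#' chromosome counts) to be diploid.
#'
#' @param diploid_two_c vector of 2C values (pg) of diploid reference
#'   accessions.
#' @return 1Cx in pg.
#' @export
calibrate_1cx <- function(diploid_two_c) {
  if (any(diploid_two_c <= 0)) stop("2C values must be positive")
  mean(diploid_two_c) / 2
}

#' Packaged flow-cytometry 2C table
#'
#' Loads the packaged reference table of flow-cytometry genome-size
#' measurements for the *Kalanchoe x houghtonii* hybrid complex, its
#' parental species and closely related taxa: 42 accessions with their
#' 2C value (pg), coefficient of variation (%) and the published ploidy
#' label.
#'
#' @param path optional path to an alternative TSV with columns
#'   `sample`, `two_c_pg`, `cv_percent`, `ploidy_label`.
#' @return data.frame with those four columns.
#' @export
flow_cytometry_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kalanchoe_2c_values.tsv",
                        package = "cloneploid", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Ploidy calls for a whole 2C table
#'
#' Calibrates 1Cx from named diploid reference accessions and classifies
#' every row of the table.
#'
#' @param tab data.frame as returned by [flow_cytometry_table()].
#' @param diploid_ref_ids sample ids of the diploid calibration
#'   accessions (must appear in `tab$sample`).
#' @param band passed to [classify_ploidy()].
#' @return `tab` with columns `ratio`, `ploidy`, `label`, `ambiguous`
#'   appended, plus attribute `one_cx`.
#' @export
ploidy_call_table <- function(tab, diploid_ref_ids, band = 0.5) {
  miss <- setdiff(diploid_ref_ids, tab$sample)
  if (length(miss)) stop("unknown reference ids: ",
                         paste(miss, collapse = ", "))
  one_cx <- calibrate_1cx(tab$two_c_pg[tab$sample %in% diploid_ref_ids])
  cls <- classify_ploidy(tab$two_c_pg, one_cx, band = band)
  out <- cbind(tab, cls[, c("ratio", "ploidy", "label", "ambiguous")])
  attr(out, "one_cx") <- one_cx
  out
}
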