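#' @importFrom utils read.delim write.table
NULL

ANNOT_FIELDS <- c("QD", "FS", "SOR", "MQ", "MQRankSum", "DP",
                  "ReadPosRankSum")

# Per-site INFO annotations for the simulated cohort. Passing sites draw
# values from safe ranges well inside the hard-filter thresholds; a
# `fail_fraction` of SNP sites gets exactly one annotation pushed beyond
# its threshold (the violated criterion is recorded as truth). Indel
# records are interleaved at uniform positions to exercise the proximity
# filter. Called inside simulate_dataset's seeded stream.
sim_variants <- function(config) {
  J <- config$n_sites
  n_ind <- config$n_indels
  pos_snp <- cumsum(sample(30:45, J, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, J, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

  nominal <- function(n, mean_depth) data.frame(
    QD = stats::runif(n, 15, 35),
    FS = stats::runif(n, 0, 20),
    SOR = stats::runif(n, 0.5, 2.5),
    MQ = stats::runif(n, 50, 60),
    MQRankSum = stats::runif(n, -1.5, 1.5),
    DP = round(stats::runif(n, 0.8, 1.2) * mean_depth),
    ReadPosRankSum = stats::runif(n, -1.5, 1.5))

  ann <- nominal(J, config$mean_depth)
  fail_reason <- rep(NA_character_, J)
  n_fail <- round(config$fail_fraction * J)
  if (n_fail > 0) {
    idx <- sample.int(J, n_fail)
    why <- sample(ANNOT_FIELDS, n_fail, replace = TRUE)
    fail_reason[idx] <- why
    for (k in seq_along(idx)) {
      i <- idx[k]
      ann[i, why[k]] <- switch(why[k],
        QD = stats::runif(1, 0, 9.9),
        FS = stats::runif(1, 61, 120),
        SOR = stats::runif(1, 3.1, 6),
        MQ = stats::runif(1, 20, 39.9),
        MQRankSum = sample(c(-1, 1), 1) * stats::runif(1, 2.6, 5),
        DP = round(stats::runif(1, 2.05, 3) * config$mean_depth),
        ReadPosRankSum = stats::runif(1, 2.6, 5))
    }
  }
  snps <- data.frame(chrom = "chr1", pos = pos_snp, ref = ref, alt = alt,
                     type = "SNP", ann, fail_reason = fail_reason,
                     stringsAsFactors = FALSE)
  if (n_ind > 0) {
    pos_ind <- sort(sample.int(max(pos_snp), n_ind))
    iref <- sample(bases, n_ind, replace = TRUE)
    indels <- data.frame(chrom = "chr1", pos = pos_ind,
                         ref = paste0(iref, sample(bases, n_ind,
                                                   replace = TRUE)),
                         alt = iref, type = "indel",
                         nominal(n_ind, config$mean_depth),
                         fail_reason = NA_character_,
                         stringsAsFactors = FALSE)
    out <- rbind(snps, indels)
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  snps
}

# Per-genotype GQ and DP for every sample x record; simulated calls are
# confidently genotyped so draws sit above the masking thresholds.
sim_genotype_quality <- function(n_samples, n_records) {
  list(gq = matrix(sample(60:99, n_samples * n_records, replace = TRUE),
                   nrow = n_samples),
       dp = matrix(sample(20:100, n_samples * n_records, replace = TRUE),
                   nrow = n_samples))
}

format_gt <- function(dosage, ploidy) {
  if (is.na(dosage)) return(paste(rep(".", ploidy), collapse = "/"))
  paste(c(rep("0", ploidy - dosage), rep("1", dosage)), collapse = "/")
}

#' Write a simulated cohort as VCF, metadata TSV and plastome FASTA
#'
#' Serializes a [simulate_dataset()] result: a VCF 4.2 file with
#' biallelic SNP records (site annotations QD, FS, SOR, MQ, MQRankSum,
#' DP, ReadPosRankSum in INFO; GT/GQ/DP per genotype, GT strings at each
#' sample's ploidy), any interleaved indel records, a sample metadata
#' table, and the aligned plastome haplotypes. The header carries no
#' timestamp, so a fixed simulation seed yields byte-identical files.
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, a named character vector of the written paths
#'   (`vcf`, `metadata`, `plastome`).
#' @export
write_sim_vcf <- function(sim, dir, prefix = "cohort") {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- sim$variants
  geno <- sim$genotypes$dosage
  ploidy <- sim$genotypes$ploidy
  n <- nrow(geno)
  snp_rows <- which(v$type == "SNP")

  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr1,length=%d>", max(v$pos) + 100L),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias (phred)\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))

  info <- sprintf(
    "QD=%.2f;FS=%.2f;SOR=%.2f;MQ=%.2f;MQRankSum=%.2f;DP=%d;ReadPosRankSum=%.2f",
    v$QD, v$FS, v$SOR, v$MQ, v$MQRankSum, as.integer(v$DP),
    v$ReadPosRankSum)

  recs <- character(nrow(v))
  snp_of_record <- match(seq_len(nrow(v)), snp_rows)
  for (r in seq_len(nrow(v))) {
    j <- snp_of_record[r]
    cells <- vapply(seq_len(n), function(i) {
      d <- if (is.na(j)) 0L else geno[i, j]
      sprintf("%s:%d:%d", format_gt(d, ploidy[i]),
              sim$gq[i, r], sim$dp[i, r])
    }, "")
    recs[r] <- paste(c(v$chrom[r], v$pos[r], ".", v$ref[r], v$alt[r],
                       ".", "PASS", info[r], "GT:GQ:DP", cells),
                     collapse = "\t")
  }

  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  con <- file(vcf_path, open = "wb")  # binary mode: fixed "\n", stable bytes
  on.exit(close(con))
  writeLines(c(hdr, recs), con, sep = "\n")

  meta_path <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  write.table(sim$metadata, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  fa_path <- file.path(dir, paste0(prefix, "_plastomes.fasta"))
  seqs <- c(list(ref_A = sim$plastome_refs$A, ref_B = sim$plastome_refs$B),
            stats::setNames(lapply(seq_len(n),
                                   function(i) sim$plastomes[i, ]),
                            rownames(sim$plastomes)))
  write_fasta(seqs, fa_path)
  invisible(c(vcf = vcf_path, metadata = meta_path, plastome = fa_path))
}

write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(names(seqs), function(nm)
    c(paste0(">", nm), paste(seqs[[nm]], collapse = ""))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

#' Read a VCF of biallelic SNP calls into dosage form
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) into the package's working
#' representation: a per-site table with the hard-filter annotations, an
#' alternate-allele dosage matrix (samples x records, `NA` for missing
#' calls), per-genotype GQ/DP matrices and a per-sample ploidy vector
#' inferred from the GT allele counts.
#'
#' @param path path to a `.vcf` (or `.vcf.gz`) file.
#' @return List of class `vcf_data` with elements `sites`, `dosage`,
#'   `gq`, `dp`, `ploidy`.
#' @export
read_dosage_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  multi <- grepl(",", sites$alt)
  sites$type <- ifelse(multi, "other",
                       ifelse(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L,
                              "SNP", "indel"))
  for (f in ANNOT_FIELDS)
    sites[[f]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = f)))

  gt <- vcfR::extract.gt(v, "GT")
  miss <- is.na(gt) | grepl("\\.", gt)
  dosage <- nchar(gsub("[^1]", "", gt))
  dosage[miss] <- NA_integer_
  nall <- nchar(gsub("[^/|]", "", gt)) + 1L
  nall[is.na(gt)] <- NA_integer_
  ploidy <- apply(nall, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) 2L else as.integer(max(x))
  })
  num_mat <- function(x) {
    out <- suppressWarnings(matrix(as.numeric(x), nrow(x), ncol(x),
                                   dimnames = dimnames(x)))
    t(out)
  }
  gq <- num_mat(vcfR::extract.gt(v, "GQ"))
  dp <- num_mat(vcfR::extract.gt(v, "DP"))
  dosage <- t(dosage)
  storage.mode(dosage) <- "integer"
  structure(list(sites = sites, dosage = dosage, gq = gq, dp = dp,
                 ploidy = ploidy), class = "vcf_data")
}

#' Read an aligned haplotype FASTA
#'
#' Thin wrapper over [ape::read.FASTA()] returning upper-case character
#' vectors, one per sequence, all of equal length.
#'
#' @param path FASTA file of aligned, equal-length sequences.
#' @return Named list of character vectors.
#' @export
read_haplotypes <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- lapply(as.character(dna), toupper)
  if (length(unique(lengths(seqs))) > 1L)
    stop("haplotypes are not aligned to equal length")
  seqs
}
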