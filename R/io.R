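#' Read genotypes as a risk-allele dosage matrix
#'
#' Accepts either a VCF (GT fields; parsed with the vcfR package) or a plain
#' dosage table (TSV: first column the individual ID, remaining columns one
#' rsID each with values 0/1/2 or empty/NA for missing). VCF genotypes are
#' converted to risk-allele dosages against the panel: the REF/ALT pair must
#' match the panel's risk/other alleles (in either orientation); multi-allelic
#' records are rejected, allele mismatches raise an error listing the
#' offending rsIDs, and strand-ambiguous A/T or C/G SNPs produce a warning
#' rather than a silent flip guess.
#'
#' @param path VCF (`.vcf`) or dosage TSV path.
#' @param panel a [SNPPanel-class], required for VCF input.
#' @return A [GenotypeMatrix-class] with sample order preserved.
#' @export
readGenotypes <- function(path, panel = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (is.null(panel)) stop("a panel is required to orient VCF alleles", call. = FALSE)
    .readVcfDosage(path, panel)
  } else {
    .readDosageTsv(path)
  }
}

.readDosageTsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "numeric"
  rownames(d) <- ids
  new("GenotypeMatrix", dosage = d)
}

.readVcfDosage <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.matrix(fix)) fix <- t(as.matrix(fix))
  snp_ids <- fix[, "ID"]
  if (anyDuplicated(snp_ids)) {
    stop("rsID(s) present more than once in VCF: ",
      paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  multi <- grepl(",", alt) | nchar(ref) > 1 | nchar(alt) > 1
  if (any(multi)) {
    stop("multi-allelic or non-SNP record(s): ",
      paste(snp_ids[multi], collapse = ", "),
      call. = FALSE
    )
  }
  keep <- snp_ids %in% rsids(panel)
  if (!any(keep)) stop("no panel SNPs found in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  snp_ids <- snp_ids[keep]; ref <- ref[keep]; alt <- alt[keep]
  risk <- riskAlleles(panel)[snp_ids]
  other <- otherAlleles(panel)[snp_ids]
  ambiguous <- (risk == "A" & other == "T") | (risk == "T" & other == "A") |
    (risk == "C" & other == "G") | (risk == "G" & other == "C")
  if (any(ambiguous)) {
    warning("strand-ambiguous A/T or C/G SNP(s), orientation taken at face value: ",
      paste(snp_ids[ambiguous], collapse = ", "),
      call. = FALSE
    )
  }
  match_fwd <- ref == other & alt == risk
  match_rev <- ref == risk & alt == other
  bad <- !(match_fwd | match_rev)
  if (any(bad)) {
    stop("VCF alleles do not match the panel at: ",
      paste(sprintf("%s (VCF %s/%s, panel %s/%s)",
        snp_ids[bad], ref[bad], alt[bad], risk[bad], other[bad]
      ), collapse = "; "),
      call. = FALSE
    )
  }
  # count ALT alleles from GT, then orient to the risk allele
  alt_count <- function(x) {
    if (is.na(x)) return(NA_real_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  d <- matrix(
    vapply(as.vector(gt), alt_count, numeric(1)),
    nrow = nrow(gt), dimnames = list(snp_ids, colnames(gt))
  )
  # where REF is the risk allele, risk dosage = 2 - ALT count
  d[match_rev, ] <- 2 - d[match_rev, , drop = FALSE]
  d <- t(d)
  new("GenotypeMatrix", dosage = d)
}

#' Write genotypes as a dosage TSV
#'
#' First column `id`, one column per rsID; missing dosages are written as NA.
#' Round-trips exactly through [readGenotypes()].
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDosageTsv <- function(genotypes, path) {
  d <- dosage(genotypes)
  tab <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write genotypes as a minimal GT-only VCF
#'
#' One arbitrary contig (`1`), positions in panel order, REF = other allele,
#' ALT = risk allele, unphased diploid GT fields. Plain uncompressed VCFv4.2
#' text, readable by [readGenotypes()] (via vcfR) and standard tools.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param panel a [SNPPanel-class] supplying the alleles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(genotypes, panel, path) {
  d <- dosage(genotypes)
  absent <- setdiff(colnames(d), rsids(panel))
  if (length(absent)) {
    stop("genotype rsID(s) not in panel: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  risk <- riskAlleles(panel)[colnames(d)]
  other <- otherAlleles(panel)[colnames(d)]
  gt_code <- c("0/0", "0/1", "1/1") # index by dosage + 1 (ALT = risk)
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", rownames(d)
    ), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(d)), function(j) {
    gts <- ifelse(is.na(d[, j]), "./.", gt_code[d[, j] + 1])
    paste(c(
      "1", j * 1000L, colnames(d)[j], other[j], risk[j], ".", "PASS", ".",
      "GT", gts
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a cohort table as CSV
#'
#' @param cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV path.
#' @return data.frame with `sex` as a factor when present.
#' @export
readCohort <- function(path) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  if ("sex" %in% names(cohort)) {
    cohort$sex <- factor(cohort$sex, levels = unique(c("girl", "boy", cohort$sex)))
    cohort$sex <- droplevels(cohort$sex)
  }
  cohort
}

#' Write an effect spec (ground truth) as JSON
#'
#' @param spec an [effectSpec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEffectSpecJson <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}
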