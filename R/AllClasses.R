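#' SNPPanel: the SNP catalogue every score is computed against
#'
#' An ordered catalogue of biallelic SNPs with their risk alleles and two
#' published per-allele effect-size columns: `betaSpeliotes` (per-allele BMI
#' effect, kg/m^2, from the 2010 GIANT GWAS meta-analysis, locus-level values
#' with proxy SNPs inheriting the index SNP's effect) and `betaFinhit`
#' (cohort-specific re-estimates; the packaged default sets them equal to
#' `betaSpeliotes`, making the ratio scheme identically 1, because the
#' original cohort weights are not publicly printed).
#'
#' @slot rsid character, unique rsIDs, order defines panel order.
#' @slot riskAllele character, single base per SNP (the BMI-increasing allele).
#' @slot otherAllele character, single base, different from `riskAllele`.
#' @slot betaSpeliotes numeric, strictly positive per-allele effects.
#' @slot betaFinhit numeric per-allele effects.
#' @slot gene character, nearest-gene label.
#'
#' @seealso [loadPanel()], [defaultPanel()]
#' @export
setClass("SNPPanel",
  representation(
    rsid = "character",
    riskAllele = "character",
    otherAllele = "character",
    betaSpeliotes = "numeric",
    betaFinhit = "numeric",
    gene = "character"
  )
)

setValidity("SNPPanel", function(object) {
  n <- length(object@rsid)
  msgs <- character()
  lens <- c(
    riskAllele = length(object@riskAllele),
    otherAllele = length(object@otherAllele),
    betaSpeliotes = length(object@betaSpeliotes),
    betaFinhit = length(object@betaFinhit),
    gene = length(object@gene)
  )
  if (any(lens != n)) {
    msgs <- c(msgs, "all slots must have the same length as 'rsid'")
  }
  if (anyDuplicated(object@rsid)) {
    msgs <- c(msgs, sprintf(
      "duplicated rsIDs: %s",
      paste(unique(object@rsid[duplicated(object@rsid)]), collapse = ", ")
    ))
  }
  bases <- c("A", "C", "G", "T")
  if (all(lens == n) && n > 0) {
    if (!all(object@riskAllele %in% bases) || !all(object@otherAllele %in% bases)) {
      msgs <- c(msgs, "alleles must be single bases A/C/G/T")
    }
    if (any(object@riskAllele == object@otherAllele)) {
      msgs <- c(msgs, "risk and other allele must differ")
    }
    if (any(!is.finite(object@betaSpeliotes)) || any(object@betaSpeliotes <= 0)) {
      msgs <- c(msgs, "betaSpeliotes must be finite and strictly positive")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' GenotypeMatrix: individuals x SNPs risk-allele dosages
#'
#' Dosages count copies of the panel risk allele: 0, 1 or 2, with `NA` for a
#' missing genotype. Rows are individuals, columns SNPs (rsIDs).
#'
#' @slot dosage numeric matrix with values in \{0, 1, 2, NA\}; rownames are
#'   individual IDs, colnames rsIDs.
#' @export
setClass("GenotypeMatrix", representation(dosage = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  msgs <- character()
  if (is.null(rownames(d)) || is.null(colnames(d))) {
    msgs <- c(msgs, "dosage matrix needs individual IDs as rownames and rsIDs as colnames")
  }
  if (anyDuplicated(rownames(d))) msgs <- c(msgs, "duplicated individual IDs")
  if (anyDuplicated(colnames(d))) msgs <- c(msgs, "duplicated rsIDs")
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' ScoreVector: one genetic risk score per individual
#'
#' @slot individualIds character.
#' @slot values numeric; unweighted scores are integer risk-allele counts,
#'   weighted schemes are the PLINK-style average score per non-missing SNP.
#' @slot scheme one of `"unweighted"`, `"speliotes"`, `"finhit"`, `"ratio"`.
#' @slot nNonmissing integer, SNPs contributing per individual.
#' @export
setClass("ScoreVector",
  representation(
    individualIds = "character",
    values = "numeric",
    scheme = "character",
    nNonmissing = "integer"
  )
)

setValidity("ScoreVector", function(object) {
  msgs <- character()
  n <- length(object@individualIds)
  if (length(object@values) != n || length(object@nNonmissing) != n) {
    msgs <- c(msgs, "values and nNonmissing must match individualIds in length")
  }
  if (length(object@scheme) != 1 ||
    !object@scheme %in% c("unweighted", "speliotes", "finhit", "ratio")) {
    msgs <- c(msgs, "scheme must be one of unweighted/speliotes/finhit/ratio")
  }
  if (any(object@nNonmissing < 1L, na.rm = TRUE)) {
    msgs <- c(msgs, "each individual must have at least one non-missing SNP")
  }
  if (length(msgs)) msgs else TRUE
})

#' FoodGRS: a food item plus the SNP subset driving its interaction
#'
#' Records the outcome of the per-SNP screening cascade for one food: the
#' ordered rsID subset selected at p < 0.2 with interaction sign matching the
#' whole-GRS reference direction. Scoring an individual against a `FoodGRS`
#' is the unweighted risk-allele count over its subset (see [subsetScore()]).
#'
#' @slot food character, the food item.
#' @slot rsids character, non-empty, duplicate-free, panel order preserved.
#' @slot referenceDirection numeric, +1 or -1: the sign of the whole-GRS x
#'   food interaction coefficient the subset was filtered against.
#' @export
setClass("FoodGRS",
  representation(
    food = "character",
    rsids = "character",
    referenceDirection = "numeric"
  )
)

setValidity("FoodGRS", function(object) {
  msgs <- character()
  if (length(object@food) != 1) msgs <- c(msgs, "food must be a single item name")
  if (length(object@rsids) < 1) msgs <- c(msgs, "rsid subset must be non-empty")
  if (anyDuplicated(object@rsids)) msgs <- c(msgs, "duplicated rsIDs in subset")
  if (length(object@referenceDirection) != 1 ||
    !object@referenceDirection %in% c(-1, 1)) {
    msgs <- c(msgs, "referenceDirection must be +1 or -1")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SNPPanel", function(object) {
  cat(sprintf("SNPPanel with %d SNPs\n", length(object@rsid)))
  k <- min(4L, length(object@rsid))
  if (k > 0) {
    cat(sprintf(
      "  %s%s\n", paste(object@rsid[seq_len(k)], collapse = ", "),
      if (length(object@rsid) > k) ", ..." else ""
    ))
  }
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf(
    "GenotypeMatrix: %d individuals x %d SNPs (%.2f%% missing)\n",
    nrow(object@dosage), ncol(object@dosage),
    100 * mean(is.na(object@dosage))
  ))
})

setMethod("show", "ScoreVector", function(object) {
  cat(sprintf(
    "ScoreVector (%s): %d individuals, mean %.3f\n",
    object@scheme, length(object@values), mean(object@values)
  ))
})

setMethod("show", "FoodGRS", function(object) {
  cat(sprintf(
    "FoodGRS for '%s': %d SNPs, reference direction %+d\n",
    object@food, length(object@rsids), as.integer(object@referenceDirection)
  ))
  cat("  ", paste(object@rsids, collapse = ", "), "\n", sep = "")
})
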