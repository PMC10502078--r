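#' Accessors for foodGRS core classes
#'
#' `rsids()` returns the rsID list of a panel, genotype matrix or food-specific
#' GRS; `individualIds()` the individual IDs; `dosage()` the numeric dosage
#' matrix; `scores()` the per-individual score values; `scoreScheme()` the
#' weighting scheme; `nNonmissing()` the per-individual count of contributing
#' SNPs; `riskAlleles()` / `otherAlleles()` / `effectSizes()` the panel columns;
#' `foodItem()` and `referenceDirection()` the `FoodGRS` fields.
#'
#' @param x a [SNPPanel-class], [GenotypeMatrix-class], [ScoreVector-class]
#'   or [FoodGRS-class] object, as appropriate.
#' @param scheme for `effectSizes()`: `"speliotes"` or `"finhit"`.
#' @return A vector or matrix of the requested field.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rsids", function(x) standardGeneric("rsids"))
#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("scoreScheme", function(x) standardGeneric("scoreScheme"))
#' @rdname accessors
#' @export
setGeneric("nNonmissing", function(x) standardGeneric("nNonmissing"))
#' @rdname accessors
#' @export
setGeneric("riskAlleles", function(x) standardGeneric("riskAlleles"))
#' @rdname accessors
#' @export
setGeneric("otherAlleles", function(x) standardGeneric("otherAlleles"))
#' @rdname accessors
#' @export
setGeneric("effectSizes", function(x, scheme = c("speliotes", "finhit")) {
  standardGeneric("effectSizes")
})
#' @rdname accessors
#' @export
setGeneric("foodItem", function(x) standardGeneric("foodItem"))
#' @rdname accessors
#' @export
setGeneric("referenceDirection", function(x) standardGeneric("referenceDirection"))

#' @rdname accessors
#' @export
setMethod("rsids", "SNPPanel", function(x) x@rsid)
#' @rdname accessors
#' @export
setMethod("rsids", "GenotypeMatrix", function(x) colnames(x@dosage))
#' @rdname accessors
#' @export
setMethod("rsids", "FoodGRS", function(x) x@rsids)
#' @rdname accessors
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@dosage))
#' @rdname accessors
#' @export
setMethod("individualIds", "ScoreVector", function(x) x@individualIds)
#' @rdname accessors
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)
#' @rdname accessors
#' @export
setMethod("scores", "ScoreVector", function(x) {
  setNames(x@values, x@individualIds)
})
#' @rdname accessors
#' @export
setMethod("scoreScheme", "ScoreVector", function(x) x@scheme)
#' @rdname accessors
#' @export
setMethod("nNonmissing", "ScoreVector", function(x) {
  setNames(x@nNonmissing, x@individualIds)
})
#' @rdname accessors
#' @export
setMethod("riskAlleles", "SNPPanel", function(x) setNames(x@riskAllele, x@rsid))
#' @rdname accessors
#' @export
setMethod("otherAlleles", "SNPPanel", function(x) setNames(x@otherAllele, x@rsid))
#' @rdname accessors
#' @export
setMethod("effectSizes", "SNPPanel", function(x, scheme = c("speliotes", "finhit")) {
  scheme <- match.arg(scheme)
  setNames(if (scheme == "speliotes") x@betaSpeliotes else x@betaFinhit, x@rsid)
})
#' @rdname accessors
#' @export
setMethod("foodItem", "FoodGRS", function(x) x@food)
#' @rdname accessors
#' @export
setMethod("referenceDirection", "FoodGRS", function(x) x@referenceDirection)

#' @rdname accessors
#' @export
setMethod("length", "SNPPanel", function(x) length(x@rsid))

#' Subset a SNP panel by position or rsID, preserving order
#'
#' @param x a [SNPPanel-class].
#' @param i integer, logical or character (rsID) index.
#' @param j,drop,... ignored.
#' @return A `SNPPanel` with the selected entries.
#' @export
setMethod("[", "SNPPanel", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) {
    miss <- setdiff(i, x@rsid)
    if (length(miss)) {
      stop("unknown rsID(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    i <- match(i, x@rsid)
  }
  new("SNPPanel",
    rsid = x@rsid[i], riskAllele = x@riskAllele[i],
    otherAllele = x@otherAllele[i], betaSpeliotes = x@betaSpeliotes[i],
    betaFinhit = x@betaFinhit[i], gene = x@gene[i]
  )
})

#' Coerce a SNPPanel to a data.frame
#'
#' @param x a [SNPPanel-class].
#' @param ... ignored.
#' @return A data.frame with one row per SNP.
#' @export
as.data.frame.SNPPanel <- function(x, ...) {
  data.frame(
    rsid = x@rsid, risk_allele = x@riskAllele, other_allele = x@otherAllele,
    beta_speliotes = x@betaSpeliotes, beta_finhit = x@betaFinhit,
    gene = x@gene, stringsAsFactors = FALSE
  )
}
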