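#' Compute a whole-panel genetic risk score
#'
#' Four schemes are supported. `unweighted` is the plain risk-allele count
#' over non-missing SNPs. The weighted schemes follow the PLINK `--score`
#' convention of averaging over non-missing SNPs: the score is
#' `sum(w_j * dosage_j) / n_nonmissing`, with weights taken from the panel's
#' `beta_speliotes` column (`speliotes`), `beta_finhit` column (`finhit`), or
#' their per-SNP ratio `beta_finhit / beta_speliotes` (`ratio`). Set
#' `perAllele = TRUE` to divide by the number of non-missing alleles
#' (2 x n_nonmissing) instead, matching PLINK's default denominator exactly.
#'
#' Individuals with every panel SNP missing cannot be scored; they are dropped
#' with a warning.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param panel a [SNPPanel-class]; every panel rsID must be present in
#'   `genotypes`.
#' @param scheme `"unweighted"`, `"speliotes"`, `"finhit"` or `"ratio"`.
#' @param perAllele logical; average weighted schemes per non-missing allele
#'   rather than per non-missing SNP.
#' @return A [ScoreVector-class].
#' @examples
#' panel <- defaultPanel()
#' g <- simulateGenotypes(panel, n = 20, seed = 1)
#' grsScore(g, panel, "unweighted")
#' @export
grsScore <- function(genotypes, panel,
                     scheme = c("unweighted", "speliotes", "finhit", "ratio"),
                     perAllele = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(is(genotypes, "GenotypeMatrix"), is(panel, "SNPPanel"))
  d <- dosage(genotypes)
  absent <- setdiff(rsids(panel), colnames(d))
  if (length(absent)) {
    stop(
      "panel rsID(s) absent from genotypes: ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  d <- d[, rsids(panel), drop = FALSE]
  w <- switch(scheme,
    unweighted = rep(1, length(panel)),
    speliotes  = panel@betaSpeliotes,
    finhit     = panel@betaFinhit,
    ratio      = panel@betaFinhit / panel@betaSpeliotes
  )
  nonmiss <- rowSums(!is.na(d))
  all_missing <- nonmiss == 0L
  if (any(all_missing)) {
    warning(
      sum(all_missing), " individual(s) with all panel SNPs missing ",
      "excluded from scoring: ",
      paste(rownames(d)[all_missing], collapse = ", "),
      call. = FALSE
    )
    d <- d[!all_missing, , drop = FALSE]
    nonmiss <- nonmiss[!all_missing]
  }
  wsum <- as.vector(ifelse(is.na(d), 0, d) %*% w)
  values <- if (scheme == "unweighted") {
    wsum
  } else if (perAllele) {
    wsum / (2 * nonmiss)
  } else {
    wsum / nonmiss
  }
  new("ScoreVector",
    individualIds = rownames(d), values = values,
    scheme = scheme, nNonmissing = as.integer(nonmiss)
  )
}

#' Score a SNP subset (food-specific GRS)
#'
#' Restricts the panel to `rsidsKeep` (which must all belong to the panel) and
#' scores as [grsScore()] does. The default unweighted scheme is the
#' food-specific GRS: the plain risk-allele count over the selected subset.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param panel a [SNPPanel-class].
#' @param rsidsKeep character vector of rsIDs, a subset of the panel.
#' @param scheme,perAllele as in [grsScore()].
#' @return A [ScoreVector-class].
#' @export
subsetScore <- function(genotypes, panel, rsidsKeep,
                        scheme = "unweighted", perAllele = FALSE) {
  unknown <- setdiff(rsidsKeep, rsids(panel))
  if (length(unknown)) {
    stop(
      "rsID(s) not in panel: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  # keep panel order, not request order
  keep <- rsids(panel)[rsids(panel) %in% rsidsKeep]
  grsScore(genotypes, panel[keep], scheme = scheme, perAllele = perAllele)
}

#' Dichotomize an unweighted GRS at the cohort median
#'
#' Individuals with a risk-allele count at or below the median are labelled
#' `low`, the rest `high`; the median itself always falls in the low group.
#'
#' @param score a [ScoreVector-class] (typically unweighted) or numeric vector.
#' @return A list with `group` (factor `low`/`high`, named by individual ID
#'   when available) and `cutoff` (the median).
#' @examples
#' dichotomize(c(a = 1, b = 2, c = 3))$group # low low high
#' @export
dichotomize <- function(score) {
  values <- if (is(score, "ScoreVector")) scores(score) else score
  if (length(values) == 0) stop("cannot dichotomize an empty score vector", call. = FALSE)
  if (length(values) < 2) stop("need at least 2 individuals to dichotomize", call. = FALSE)
  cutoff <- median(values, na.rm = TRUE)
  group <- factor(
    ifelse(values <= cutoff, "low", "high"),
    levels = c("low", "high")
  )
  names(group) <- names(values)
  if (all(group == "low")) {
    warning("all individuals fall in the low group (constant or degenerate scores)",
      call. = FALSE
    )
  }
  list(group = group, cutoff = cutoff)
}
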