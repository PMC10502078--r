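#' Load a SNP panel from a TSV file
#'
#' The panel file is tab-separated with header columns `rsid`, `risk_allele`,
#' `other_allele`, `beta_speliotes`, `beta_finhit` and `gene`. Row order is
#' preserved and defines the panel order used everywhere downstream.
#'
#' @param path path to the panel TSV.
#' @return A [SNPPanel-class] object.
#' @examples
#' panel <- defaultPanel()
#' length(panel) # 30
#' @export
loadPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c(
    "rsid", "risk_allele", "other_allele",
    "beta_speliotes", "beta_finhit", "gene"
  )
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(
      "panel file is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(tab$rsid)) {
    stop(
      "duplicated rsID(s) in panel file: ",
      paste(unique(tab$rsid[duplicated(tab$rsid)]), collapse = ", "),
      call. = FALSE
    )
  }
  new("SNPPanel",
    rsid = as.character(tab$rsid),
    riskAllele = toupper(as.character(tab$risk_allele)),
    otherAllele = toupper(as.character(tab$other_allele)),
    betaSpeliotes = as.numeric(tab$beta_speliotes),
    betaFinhit = as.numeric(tab$beta_finhit),
    gene = as.character(tab$gene)
  )
}

#' The packaged 30-SNP childhood-BMI panel
#'
#' The default catalogue of 30 well-replicated obesity SNPs (PTBP2 rs11165643
#' through TMEM160 rs3810291) with catalogue risk alleles and locus-level
#' per-allele BMI effect sizes from the 2010 GIANT GWAS meta-analysis. The
#' `beta_finhit` column defaults to `beta_speliotes` (ratio scheme = 1); supply
#' your own panel file via [loadPanel()] to use cohort-specific weights.
#'
#' @return A [SNPPanel-class] with 30 entries.
#' @export
defaultPanel <- function() {
  loadPanel(system.file("extdata", "bmi_snp_panel.tsv",
    package = "foodGRS", mustWork = TRUE
  ))
}

#' Published food-specific GRS SNP subsets
#'
#' The seven reported food-specific SNP subsets (dark bread, biscuits and
#' cookies, sugary juice drink, sweets and chocolate, pizza, hamburger and
#' hotdog, milk and sourmilk) from a published gene-diet interaction study
#' in school-aged Finnish children,
#' as a named list of rsID character vectors. Used for the set-algebra worked
#' examples and as reference inputs.
#'
#' @return Named list of character vectors.
#' @examples
#' lists <- publishedFoodGrsSnps()
#' length(lists$pizza) # 11
#' @export
publishedFoodGrsSnps <- function() {
  tab <- read.csv(
    system.file("extdata", "finhit_food_grs_snps.csv",
      package = "foodGRS", mustWork = TRUE
    ),
    stringsAsFactors = FALSE
  )
  split(tab$rsid, factor(tab$food, levels = unique(tab$food)))
}

#' Published whole-GRS x food screening p-values
#'
#' The reported interaction p-values for 16 food items against the four
#' BMI-GRS weighting schemes, including the dichotomized-score follow-up
#' values where one was reported. Used as the worked example for
#' [applyFlagRule()].
#'
#' @return data.frame with columns `food`, `scheme`, `p_continuous`,
#'   `p_dichotomized` (NA where no dichotomized follow-up was reported).
#' @export
publishedScreenPvalues <- function() {
  read.csv(
    system.file("extdata", "finhit_screen_pvalues.csv",
      package = "foodGRS", mustWork = TRUE
    ),
    stringsAsFactors = FALSE
  )
}
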