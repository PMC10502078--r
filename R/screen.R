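#' Flagging rule for the whole-GRS screening stage
#'
#' A food is taken forward when, for any weighting scheme, either its
#' continuous-score interaction p-value or (where one was computed) its
#' dichotomized-score follow-up p-value falls below `alpha`.
#'
#' @param report data.frame with columns `food`, `p_continuous` and
#'   `p_dichotomized` (NA where no dichotomized follow-up exists), one row per
#'   food x scheme.
#' @param alpha flagging threshold, default 0.15.
#' @return Character vector of flagged foods, in order of first appearance.
#' @examples
#' flagged <- applyFlagRule(publishedScreenPvalues())
#' length(flagged) # 7
#' @export
applyFlagRule <- function(report, alpha = 0.15) {
  stopifnot(all(c("food", "p_continuous") %in% names(report)))
  if (is.null(report$p_dichotomized)) report$p_dichotomized <- NA_real_
  hit <- (!is.na(report$p_continuous) & report$p_continuous < alpha) |
    (!is.na(report$p_dichotomized) & report$p_dichotomized < alpha)
  unique(report$food[hit])
}

#' Level-1 screen: whole-GRS x food interactions
#'
#' For every food x scheme combination, fits the continuous-score interaction
#' model (adjusted for the screening covariates). When the continuous p-value
#' is borderline — inside `[alpha, borderline)` — the interaction is
#' re-examined with the scheme's score dichotomized at its median
#' (low = 0, high = 1). A food is flagged when any scheme's continuous or
#' dichotomized p-value is below `alpha` (see [applyFlagRule()]).
#'
#' @param cohort data.frame with the outcome, covariates and `weekly_<food>`
#'   columns.
#' @param genotypes a [GenotypeMatrix-class].
#' @param panel a [SNPPanel-class].
#' @param foods character, food items to test (must have `weekly_<food>`
#'   columns, or bare columns of that name).
#' @param schemes character subset of the four weighting schemes.
#' @param alpha flagging threshold for the GRS level (default 0.15).
#' @param borderline upper end of the borderline band triggering the
#'   dichotomized follow-up (default 0.25).
#' @param covariates character, cohort columns used as adjustments (default:
#'   sex, leisure-time physical activity, sleep duration and the first two
#'   principal coordinates).
#' @param outcome name of the outcome column (default `"bmiz"`).
#' @return A list with `report` (data.frame: food, scheme, interaction b,
#'   `p_continuous`, `p_dichotomized`), `flagged` (character) and
#'   `referenceDirections` (named +1/-1 per flagged food, the sign of the
#'   unweighted whole-GRS interaction, used by [screenSnps()]).
#' @export
screenWholeGrs <- function(cohort, genotypes, panel,
                           foods = ffqItems(),
                           schemes = c("unweighted", "speliotes", "finhit", "ratio"),
                           alpha = 0.15, borderline = 0.25,
                           covariates = c("sex", "ltpa", "sleep", "pc1", "pc2"),
                           outcome = "bmiz") {
  if (length(foods) == 0) stop("no foods to screen", call. = FALSE)
  schemes <- match.arg(schemes, several.ok = TRUE)
  covs <- if (length(covariates)) cohort[, covariates, drop = FALSE] else NULL
  rows <- list()
  dir_ref <- c()
  # reference direction for the per-SNP screen comes from the unweighted
  # whole-GRS fit (or the first scheme if unweighted is not requested)
  ref_scheme <- if ("unweighted" %in% schemes) "unweighted" else schemes[1]
  for (scheme in schemes) {
    sv <- grsScore(genotypes, panel, scheme)
    gv <- scores(sv)[cohort$id]
    grp <- dichotomize(sv)$group[cohort$id]
    g_dich <- as.numeric(grp == "high")
    for (food in foods) {
      e <- .foodColumn(cohort, food)
      fit <- fitInteraction(cohort[[outcome]], gv, e, covs,
        gName = "grs", eName = food
      )
      b_int <- fit$b[fit$term == "interaction"]
      p_cont <- fit$p[fit$term == "interaction"]
      p_dich <- NA_real_
      if (!is.na(p_cont) && p_cont >= alpha && p_cont < borderline) {
        fit2 <- fitInteraction(cohort[[outcome]], g_dich, e, covs,
          gName = "grs_group", eName = food
        )
        p_dich <- fit2$p[fit2$term == "interaction"]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        food = food, scheme = scheme, b = b_int,
        p_continuous = p_cont, p_dichotomized = p_dich,
        stringsAsFactors = FALSE
      )
      if (scheme == ref_scheme) dir_ref[food] <- sign(b_int)
    }
  }
  report <- do.call(rbind, rows)
  flagged <- applyFlagRule(report, alpha)
  list(
    report = report,
    flagged = flagged,
    referenceDirections = dir_ref[flagged]
  )
}

.foodColumn <- function(cohort, food) {
  col <- if (paste0("weekly_", food) %in% names(cohort)) {
    paste0("weekly_", food)
  } else if (food %in% names(cohort)) {
    food
  } else {
    stop("no weekly frequency column for food '", food, "'", call. = FALSE)
  }
  cohort[[col]]
}

#' Level-2 screen: per-SNP interactions with a flagged food
#'
#' Fits the interaction model once per panel SNP with the SNP's risk-allele
#' dosage as the genetic term, then selects the SNPs whose interaction
#' coefficient has the same sign as `referenceDirection` (the whole-GRS
#' interaction direction for this food) and p-value below `alpha`. Panel
#' order is preserved in the selection.
#'
#' @inheritParams screenWholeGrs
#' @param food a single flagged food item.
#' @param referenceDirection +1 or -1.
#' @param alpha per-SNP threshold, default 0.2.
#' @return A list with `selected` (character rsIDs, possibly empty with a
#'   warning) and `results` (data.frame rsid, b, p per SNP).
#' @export
screenSnps <- function(cohort, genotypes, panel, food, referenceDirection,
                       alpha = 0.2,
                       covariates = c("sex", "ltpa", "sleep", "pc1", "pc2"),
                       outcome = "bmiz") {
  stopifnot(referenceDirection %in% c(-1, 1))
  covs <- if (length(covariates)) cohort[, covariates, drop = FALSE] else NULL
  e <- .foodColumn(cohort, food)
  d <- dosage(genotypes)[cohort$id, , drop = FALSE]
  res <- lapply(rsids(panel), function(rs) {
    fit <- fitInteraction(cohort[[outcome]], d[, rs], e, covs,
      gName = rs, eName = food
    )
    fit[fit$term == "interaction", c("b", "p")]
  })
  results <- data.frame(
    rsid = rsids(panel),
    b = vapply(res, `[[`, numeric(1), "b"),
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  sel <- results$rsid[sign(results$b) == referenceDirection & results$p < alpha]
  if (length(sel) == 0) {
    warning("no SNP passed the screen for food '", food, "'", call. = FALSE)
  }
  list(selected = sel, results = results)
}
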