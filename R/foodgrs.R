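#' Build a food-specific GRS from the screened SNP subset
#'
#' @param panel a [SNPPanel-class].
#' @param selected character, non-empty duplicate-free rsID subset of the
#'   panel (panel order is imposed).
#' @param food the food item.
#' @param referenceDirection +1 or -1, the whole-GRS interaction sign the
#'   subset was filtered against.
#' @return A [FoodGRS-class].
#' @export
buildFoodGrs <- function(panel, selected, food, referenceDirection) {
  if (length(selected) == 0) {
    stop("cannot build a food-specific GRS from an empty selection", call. = FALSE)
  }
  if (anyDuplicated(selected)) {
    stop("duplicated rsID(s) in selection: ",
      paste(unique(selected[duplicated(selected)]), collapse = ", "),
      call. = FALSE
    )
  }
  unknown <- setdiff(selected, rsids(panel))
  if (length(unknown)) {
    stop("selection contains rsID(s) not in panel: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  new("FoodGRS",
    food = food,
    rsids = rsids(panel)[rsids(panel) %in% selected],
    referenceDirection = referenceDirection
  )
}

#' Validate a food-specific GRS in two covariate models
#'
#' Scores the cohort on the food-specific GRS (unweighted risk-allele count
#' over its SNP subset) and fits the interaction regression in two models:
#' model 1 adjusted for sex only, model 2 additionally for leisure-time
#' physical activity and sleep duration.
#'
#' @param cohort data.frame (needs `id`, the outcome, covariates, and the
#'   food's weekly column).
#' @param genotypes a [GenotypeMatrix-class].
#' @param panel a [SNPPanel-class].
#' @param fgrs a [FoodGRS-class].
#' @param models named list of covariate-name vectors; default the two
#'   standard models.
#' @param outcome outcome column name, default `"bmiz"`.
#' @return Named list (one element per model) of data.frames containing the
#'   three focal terms — score, food, interaction — with b, SE, standardized
#'   beta, t, p and 95% CI.
#' @export
validateFoodGrs <- function(cohort, genotypes, panel, fgrs,
                            models = list(
                              model1 = "sex",
                              model2 = c("sex", "ltpa", "sleep")
                            ),
                            outcome = "bmiz") {
  stopifnot(is(fgrs, "FoodGRS"))
  sv <- subsetScore(genotypes, panel, rsids(fgrs))
  gv <- scores(sv)[cohort$id]
  e <- .foodColumn(cohort, foodItem(fgrs))
  lapply(models, function(covnames) {
    fit <- fitInteraction(
      cohort[[outcome]], gv, e,
      cohort[, covnames, drop = FALSE],
      gName = "score", eName = foodItem(fgrs)
    )
    fit[fit$term %in% c("score", foodItem(fgrs), "interaction"), ]
  })
}

#' Stratified food effects in low/high genetic-risk groups
#'
#' Dichotomizes the food-specific GRS at its median (median to `low`), then
#' estimates the food's effect on the outcome separately within each group
#' (adjusted for sex, leisure-time physical activity and sleep duration, the
#' fully adjusted model), and fits the joint group x food model on the pooled
#' sample for the formal interaction test.
#'
#' @inheritParams validateFoodGrs
#' @param covariates adjustment columns, default `c("sex", "ltpa", "sleep")`.
#' @param minPerGroup smallest admissible stratum size.
#' @return A list with `by_group` (data.frame: group, b, se, p, ci_low,
#'   ci_high, n for the food term), `interaction` (b and p of group x food in
#'   the joint model) and `cutoff` (the median used).
#' @export
stratifiedEffects <- function(cohort, genotypes, panel, fgrs,
                              covariates = c("sex", "ltpa", "sleep"),
                              outcome = "bmiz", minPerGroup = 30) {
  stopifnot(is(fgrs, "FoodGRS"))
  sv <- subsetScore(genotypes, panel, rsids(fgrs))
  dich <- dichotomize(sv)
  grp <- dich$group[cohort$id]
  e <- .foodColumn(cohort, foodItem(fgrs))
  covs <- cohort[, covariates, drop = FALSE]
  if (any(table(grp) < minPerGroup)) {
    stop("a genetic-risk stratum has fewer than ", minPerGroup, " individuals",
      call. = FALSE
    )
  }
  per_group <- lapply(c("low", "high"), function(lv) {
    sel <- !is.na(grp) & grp == lv
    # within-stratum model: outcome ~ food + covariates; reuse the OLS
    # machinery with the food as the 'g' term and sex as a stand-in 'e'
    X_cov <- covs[sel, , drop = FALSE]
    fit <- .olsTerms(
      cohort[[outcome]][sel],
      data.frame(food = e[sel], X_cov)
    )
    row <- fit[fit$term == "food", ]
    data.frame(
      group = lv, b = row$b, se = row$se, p = row$p,
      ci_low = row$ci_low, ci_high = row$ci_high, n = row$n_used,
      stringsAsFactors = FALSE
    )
  })
  joint <- fitInteraction(
    cohort[[outcome]], as.numeric(grp == "high"), e, covs,
    gName = "grs_group", eName = foodItem(fgrs)
  )
  list(
    by_group = do.call(rbind, per_group),
    interaction = joint[joint$term == "interaction", ],
    cutoff = dich$cutoff
  )
}

# plain OLS of y on the columns of X (plus intercept), complete-case,
# returning the same columns as fitInteraction()
.olsTerms <- function(y, X) {
  df <- data.frame(.y = y, X)
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  mm <- model.matrix(~., data = df[, -1, drop = FALSE])
  p <- ncol(mm)
  if (nrow(mm) < p + 2) stop("insufficient complete cases", call. = FALSE)
  qrX <- qr(mm)
  if (qrX$rank < p) {
    bad <- colnames(mm)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design; offending term(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  b <- qr.coef(qrX, df$.y)
  res <- df$.y - mm %*% b
  dfres <- nrow(mm) - p
  sigma2 <- sum(res^2) / dfres
  XtX_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- b / se
  tcrit <- qt(0.975, dfres)
  data.frame(
    term = colnames(mm), b = unname(b), se = unname(se),
    t = unname(tval), p = unname(2 * pt(-abs(tval), dfres)),
    ci_low = unname(b - tcrit * se), ci_high = unname(b + tcrit * se),
    n_used = nrow(mm), row.names = NULL, stringsAsFactors = FALSE
  )
}
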