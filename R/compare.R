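#' Descriptive two-group comparisons (cohort characteristics table)
#'
#' Compares each requested variable between two groups: continuous variables
#' with an independent-samples t-test (pooled variance by default, Welch
#' optional), categorical variables with a chi-square test on the contingency
#' table. Each variable is analysed on its complete cases.
#'
#' @param cohort data.frame of per-individual variables.
#' @param groups factor/character of length `nrow(cohort)` with exactly two
#'   levels (e.g. the `low`/`high` output of [dichotomize()]).
#' @param continuous character, names of continuous columns.
#' @param categorical character, names of categorical columns.
#' @param pooled logical; pooled-variance t-test (default) or Welch.
#' @param correct logical; continuity correction for 2x2 chi-square tables
#'   (default FALSE, plain Pearson chi-square).
#' @return data.frame with one row per variable (and per level for categorical
#'   variables): group means/SDs or counts/percentages, test used, p-value.
#' @export
compareGroups <- function(cohort, groups,
                          continuous = character(),
                          categorical = character(),
                          pooled = TRUE, correct = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required", call. = FALSE)
  if (any(table(groups) == 0)) stop("both groups must be non-empty", call. = FALSE)
  if (length(groups) != nrow(cohort)) {
    stop("groups must have one label per cohort row", call. = FALSE)
  }
  lv <- levels(groups)
  rows <- list()
  for (v in continuous) {
    x <- cohort[[v]]
    ok <- !is.na(x)
    tt <- t.test(x[ok & groups == lv[1]], x[ok & groups == lv[2]],
      var.equal = pooled
    )
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = NA_character_,
      stat1 = mean(x[ok & groups == lv[1]]), stat2 = mean(x[ok & groups == lv[2]]),
      spread1 = sd(x[ok & groups == lv[1]]), spread2 = sd(x[ok & groups == lv[2]]),
      test = if (pooled) "t-test (pooled)" else "t-test (Welch)",
      p = tt$p.value, stringsAsFactors = FALSE
    )
  }
  for (v in categorical) {
    x <- factor(cohort[[v]])
    ok <- !is.na(x)
    tab <- table(x[ok], droplevels(groups[ok]))
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    for (lev in rownames(tab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev,
        stat1 = tab[lev, lv[1]], stat2 = tab[lev, lv[2]],
        spread1 = 100 * tab[lev, lv[1]] / sum(tab[, lv[1]]),
        spread2 = 100 * tab[lev, lv[2]] / sum(tab[, lv[2]]),
        test = "chi-square", p = ct$p.value, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      variable = character(), level = character(), stat1 = numeric(),
      stat2 = numeric(), spread1 = numeric(), spread2 = numeric(),
      test = character(), p = numeric(), stringsAsFactors = FALSE
    )
  }
  names(out)[3:6] <- c(
    paste0(lv[1], "_value"), paste0(lv[2], "_value"),
    paste0(lv[1], "_spread"), paste0(lv[2], "_spread")
  )
  rownames(out) <- NULL
  out
}
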