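#' Fit a gene x environment interaction regression
#'
#' Ordinary least squares for
#' `outcome ~ intercept + g + e + covariates + g:e`
#' on complete cases. Two-sided p-values come from the t distribution with
#' residual degrees of freedom; 95% CIs are `b +/- t(0.975, df) * SE`.
#' Standardized coefficients (`beta`) multiply each unstandardized coefficient
#' by `SD(term) / SD(outcome)` computed on the analysis sample; for the
#' interaction this standardizes the product term itself.
#'
#' @param outcome numeric outcome (BMI z-score).
#' @param g numeric genetic term (a GRS, a food-specific GRS, or a single-SNP
#'   dosage); a [ScoreVector-class] is accepted.
#' @param e numeric environmental exposure (weekly food frequency).
#' @param covariates data.frame (or NULL) of adjustment variables; factors are
#'   dummy-coded.
#' @param gName,eName labels used for the terms in the output.
#' @param minCases minimum excess of complete cases over parameters.
#' @return data.frame with one row per model term: `term`, `b`, `se`, `beta`,
#'   `t`, `p`, `ci_low`, `ci_high`, `n_used`.
#' @examples
#' set.seed(1)
#' g <- rbinom(200, 2, 0.4)
#' e <- rpois(200, 2)
#' y <- 1 + 0.5 * g + 0.2 * e + 0.08 * g * e + rnorm(200)
#' fit <- fitInteraction(y, g, e)
#' fit[fit$term == "interaction", ]
#' @export
fitInteraction <- function(outcome, g, e, covariates = NULL,
                           gName = "score", eName = "food", minCases = 10) {
  if (is(g, "ScoreVector")) g <- scores(g)
  outcome <- as.numeric(outcome)
  g <- as.numeric(g)
  e <- as.numeric(e)
  n <- length(outcome)
  if (length(g) != n || length(e) != n) {
    stop("outcome, g and e must have equal length", call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      stop("covariates must have one row per individual", call. = FALSE)
    }
  }
  base <- data.frame(.y = outcome, .g = g, .e = e)
  df_all <- if (is.null(covariates) || ncol(covariates) == 0) {
    base
  } else {
    cbind(base, covariates)
  }
  cc <- complete.cases(df_all)
  df_cc <- df_all[cc, , drop = FALSE]
  covar_part <- if (is.null(covariates) || ncol(covariates) == 0) {
    NULL
  } else {
    model.matrix(~., data = df_cc[, -(1:3), drop = FALSE])[, -1, drop = FALSE]
  }
  X <- cbind(
    `(Intercept)` = 1, g = df_cc$.g, e = df_cc$.e, covar_part,
    interaction = df_cc$.g * df_cc$.e
  )
  colnames(X)[colnames(X) == "g"] <- gName
  colnames(X)[colnames(X) == "e"] <- eName
  p <- ncol(X)
  if (nrow(X) < p + minCases) {
    stop(
      "insufficient complete cases (", nrow(X), ") for ", p, " parameters",
      call. = FALSE
    )
  }
  const <- apply(X[, -1, drop = FALSE], 2, function(col) var(col) == 0)
  if (any(const)) {
    stop(
      "constant predictor(s): ",
      paste(colnames(X)[-1][const], collapse = ", "),
      call. = FALSE
    )
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(
      "singular design; offending term(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  y <- df_cc$.y
  b <- qr.coef(qrX, y)
  res <- y - X %*% b
  dfres <- nrow(X) - p
  sigma2 <- sum(res^2) / dfres
  XtX_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- b / se
  pval <- 2 * pt(-abs(tval), dfres)
  tcrit <- qt(0.975, dfres)
  sdy <- sd(y)
  sdx <- apply(X, 2, sd) # intercept sd = 0 -> beta 0
  data.frame(
    term = colnames(X),
    b = unname(b),
    se = unname(se),
    beta = unname(b * sdx / sdy),
    t = unname(tval),
    p = unname(pval),
    ci_low = unname(b - tcrit * se),
    ci_high = unname(b + tcrit * se),
    n_used = nrow(X),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
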