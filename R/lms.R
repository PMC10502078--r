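#' Read an LMS reference table
#'
#' CSV with columns `sex` (`girl`/`boy` or `female`/`male`), `age` (years),
#' and the LMS parameters `L` (Box-Cox power), `M` (median BMI, kg/m^2) and
#' `S` (coefficient of variation). Ages must be strictly increasing within
#' sex, M and S strictly positive. Users typically plug in a published
#' IOTF/LMS coefficient file here.
#'
#' @param path CSV path.
#' @return data.frame with validated columns.
#' @export
readLmsReference <- function(path) {
  ref <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "age", "L", "M", "S")
  missing_cols <- setdiff(required, names(ref))
  if (length(missing_cols)) {
    stop(
      "LMS reference missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  .validateLms(ref)
}

.validateLms <- function(ref) {
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    stop("LMS reference requires M > 0 and S > 0", call. = FALSE)
  }
  for (s in unique(ref$sex)) {
    a <- ref$age[ref$sex == s]
    if (any(diff(a) <= 0)) {
      stop("LMS reference ages must be strictly increasing within sex", call. = FALSE)
    }
  }
  ref
}

#' A synthetic LMS reference for school-aged children
#'
#' A smooth, self-contained LMS table covering ages 5-18 for both sexes, with
#' median BMI rising from ~15.3 to ~21.5 kg/m^2, mild negative skewness
#' (L around -1.5) and S around 0.11. It is synthetic: adequate for
#' simulation and testing, not a published growth reference.
#'
#' @param ages numeric vector of tabulated ages (years).
#' @return data.frame usable wherever an LMS reference is expected.
#' @export
syntheticLmsReference <- function(ages = seq(5, 18, by = 0.5)) {
  one_sex <- function(sex, m_shift) {
    data.frame(
      sex = sex,
      age = ages,
      L = -1.5 + 0.02 * (ages - 11),
      M = 15.3 + 0.45 * (ages - 5) + m_shift,
      S = 0.11 + 0.002 * (ages - 11)
    )
  }
  .validateLms(rbind(one_sex("girl", 0.1), one_sex("boy", 0)))
}

.interpLms <- function(age, sex, ref) {
  sex <- as.character(sex)
  # normalize common sex encodings
  sex[sex %in% c("female", "F", "f", "2")] <- "girl"
  sex[sex %in% c("male", "M", "m", "1")] <- "boy"
  out <- matrix(NA_real_, nrow = length(age), ncol = 3,
    dimnames = list(NULL, c("L", "M", "S"))
  )
  for (s in unique(sex)) {
    sel <- sex == s
    sub <- ref[ref$sex == s, ]
    if (nrow(sub) == 0) stop("sex '", s, "' not in LMS reference", call. = FALSE)
    if (any(age[sel] < min(sub$age) | age[sel] > max(sub$age))) {
      stop("age outside LMS reference range for sex '", s, "'", call. = FALSE)
    }
    for (p in c("L", "M", "S")) {
      out[sel, p] <- approx(sub$age, sub[[p]], xout = age[sel])$y
    }
  }
  out
}

#' BMI-for-age z-score via the LMS transformation
#'
#' With (L, M, S) interpolated linearly in age within sex,
#' `z = ((bmi/M)^L - 1) / (L * S)` when `L != 0`, and
#' `z = log(bmi/M) / S` when `L == 0`.
#'
#' @param bmi numeric, kg/m^2, strictly positive.
#' @param age numeric, years, within the reference range.
#' @param sex character/factor, matching the reference's sex labels
#'   (`girl`/`boy`; `female`/`male`, `F`/`M` and `1`/`2` are normalized).
#' @param ref LMS reference data.frame ([readLmsReference()] or
#'   [syntheticLmsReference()]).
#' @return Numeric z-scores.
#' @examples
#' ref <- syntheticLmsReference()
#' bmiZscore(18, 11, "girl", ref)
#' @export
bmiZscore <- function(bmi, age, sex, ref = syntheticLmsReference()) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be finite and strictly positive", call. = FALSE)
  }
  ref <- .validateLms(ref)
  lms <- .interpLms(age, sex, ref)
  L <- lms[, "L"]; M <- lms[, "M"]; S <- lms[, "S"]
  unname(ifelse(abs(L) < 1e-12,
    log(bmi / M) / S,
    ((bmi / M)^L - 1) / (L * S)
  ))
}

#' Invert the LMS transformation (z-score to BMI)
#'
#' @param z numeric z-scores.
#' @inheritParams bmiZscore
#' @return Numeric BMI values, kg/m^2.
#' @export
bmiFromZscore <- function(z, age, sex, ref = syntheticLmsReference()) {
  ref <- .validateLms(ref)
  lms <- .interpLms(age, sex, ref)
  L <- lms[, "L"]; M <- lms[, "M"]; S <- lms[, "S"]
  unname(ifelse(abs(L) < 1e-12,
    M * exp(S * z),
    M * (1 + L * S * z)^(1 / L)
  ))
}
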