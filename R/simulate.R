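#' Specify the ground truth of a synthetic cohort
#'
#' Collects the true generative effects for [simulateBmiz()]: per-SNP main
#' effects (BMIz units per risk allele), food main effects (BMIz per
#' times/week), SNP x food interaction effects (BMIz per risk-allele x
#' times/week), covariate effects, residual noise SD and the master seed.
#'
#' @param snpMainEffects named numeric, rsID -> effect (may be empty).
#' @param foodMainEffects named numeric, food item -> effect.
#' @param interactionEffects data.frame with columns `rsid`, `food`, `effect`
#'   (or NULL).
#' @param covariateEffects named numeric, covariate column -> effect.
#' @param noiseSd residual SD, strictly positive.
#' @param seed master seed (integer).
#' @return A list of class `"EffectSpec"`.
#' @export
effectSpec <- function(snpMainEffects = numeric(),
                       foodMainEffects = numeric(),
                       interactionEffects = NULL,
                       covariateEffects = numeric(),
                       noiseSd = 1, seed = 1L) {
  if (!is.numeric(noiseSd) || length(noiseSd) != 1 || noiseSd <= 0) {
    stop("noiseSd must be a single strictly positive number", call. = FALSE)
  }
  if (!is.null(interactionEffects)) {
    stopifnot(all(c("rsid", "food", "effect") %in% names(interactionEffects)))
  }
  bad_food <- setdiff(
    c(names(foodMainEffects), interactionEffects$food),
    ffqItems()
  )
  if (length(bad_food)) {
    stop("unknown food item(s): ", paste(bad_food, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      snpMainEffects = snpMainEffects,
      foodMainEffects = foodMainEffects,
      interactionEffects = interactionEffects,
      covariateEffects = covariateEffects,
      noiseSd = noiseSd,
      seed = as.integer(seed)
    ),
    class = "EffectSpec"
  )
}

# derive independent sub-seeds from a master seed so stages can be
# regenerated independently
.subSeeds <- function(seed, n = 4) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Default risk-allele frequencies for the packaged panel
#'
#' Evenly spread frequencies from 0.25 to 0.65 across the panel (mean 0.45),
#' so the expected unweighted risk-allele count over 30 SNPs is 27 — matching
#' the median count around which the reference cohort dichotomizes.
#'
#' @param panel a [SNPPanel-class].
#' @return Named numeric vector, rsID -> frequency in (0, 1).
#' @export
defaultRiskAlleleFreqs <- function(panel = defaultPanel()) {
  setNames(
    seq(0.25, 0.65, length.out = length(panel)),
    rsids(panel)
  )
}

#' Simulate a risk-allele dosage matrix under Hardy-Weinberg proportions
#'
#' Each SNP's dosage is drawn independently as Binomial(2, freq) (no linkage
#' disequilibrium), then each entry is set missing independently with
#' probability `missingRate`.
#'
#' @param panel a [SNPPanel-class].
#' @param n number of individuals (>= 1).
#' @param freqs named risk-allele frequencies in (0, 1), one per panel rsID.
#' @param missingRate per-entry missingness probability in [0, 1).
#' @param seed integer seed; identical seeds give identical matrices.
#' @return A [GenotypeMatrix-class] with individual IDs `id0001`, ...
#' @export
simulateGenotypes <- function(panel, n, freqs = defaultRiskAlleleFreqs(panel),
                              missingRate = 0, seed = 1L) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("risk-allele frequencies must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (missingRate < 0 || missingRate >= 1) {
    stop("missingRate must be in [0, 1)", call. = FALSE)
  }
  unknown <- setdiff(names(freqs), rsids(panel))
  if (length(unknown)) {
    stop("frequencies given for rsID(s) not in panel: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  absent <- setdiff(rsids(panel), names(freqs))
  if (length(absent)) {
    stop("no frequency for panel rsID(s): ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  set.seed(seed)
  m <- length(panel)
  d <- vapply(
    rsids(panel),
    function(rs) rbinom(n, 2, freqs[[rs]]),
    numeric(n)
  )
  d <- matrix(as.numeric(d), nrow = n, dimnames = list(
    sprintf("id%04d", seq_len(n)), rsids(panel)
  ))
  if (missingRate > 0) {
    d[matrix(runif(n * m) < missingRate, nrow = n)] <- NA_real_
  }
  new("GenotypeMatrix", dosage = d)
}

#' Simulate cohort covariates and FFQ ratings
#'
#' Generates the per-individual variables the interaction analysis adjusts
#' for, with distributions resembling a Finnish school-aged cohort: age ~
#' Normal(11.3, 0.2); sex girl/boy with probability 1/2; leisure-time
#' physical activity ~ Normal(6.7, 2.7) truncated at 0 (h/week); sleep ~
#' Normal(9.8, 0.7) (h/night); two ancestry principal coordinates ~
#' Normal(0, 1); 16 FFQ ratings on the 1-7 scale drawn from per-item
#' categorical distributions calibrated to the default weekly means
#' (see [ffqRatingProbabilities()]).
#'
#' @param n cohort size (>= 1).
#' @param seed integer seed.
#' @param ffqMeans target weekly means the rating distributions are
#'   calibrated to.
#' @param ffqMissingRate per-rating missingness probability in [0, 1).
#' @return data.frame with columns `id`, `age`, `sex`, `ltpa`, `sleep`,
#'   `pc1`, `pc2` and `ffq_<item>` for the 16 items. BMIz is added later by
#'   [simulateBmiz()].
#' @export
simulateCohort <- function(n, seed = 1L,
                           ffqMeans = defaultFfqWeeklyMeans(),
                           ffqMissingRate = 0) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (ffqMissingRate < 0 || ffqMissingRate >= 1) {
    stop("ffqMissingRate must be in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  ltpa <- rnorm(n, 6.7, 2.7)
  # truncate at zero by redrawing (exact truncated normal)
  while (any(neg <- ltpa < 0)) ltpa[neg] <- rnorm(sum(neg), 6.7, 2.7)
  cohort <- data.frame(
    id = sprintf("id%04d", seq_len(n)),
    age = rnorm(n, 11.3, 0.2),
    sex = factor(ifelse(runif(n) < 0.5, "girl", "boy"), levels = c("girl", "boy")),
    ltpa = ltpa,
    sleep = rnorm(n, 9.8, 0.7),
    pc1 = rnorm(n),
    pc2 = rnorm(n),
    stringsAsFactors = FALSE
  )
  probs <- ffqRatingProbabilities(ffqMeans)
  for (item in names(ffqMeans)) {
    r <- sample.int(7L, n, replace = TRUE, prob = probs[item, ])
    if (ffqMissingRate > 0) r[runif(n) < ffqMissingRate] <- NA_integer_
    cohort[[paste0("ffq_", item)]] <- r
  }
  cohort
}

#' Add recoded weekly-frequency columns to a cohort
#'
#' @param cohort data.frame with `ffq_<item>` rating columns.
#' @param mapping rating-to-weekly mapping, see [recodeFfq()].
#' @return The cohort with `weekly_<item>` columns appended.
#' @export
addWeeklyFfq <- function(cohort, mapping = defaultFfqMapping()) {
  rating_cols <- grep("^ffq_", names(cohort), value = TRUE)
  weekly <- recodeFfq(cohort[, rating_cols, drop = FALSE], mapping)
  cbind(cohort, weekly)
}

#' Generate BMI z-scores from a linear ground-truth model
#'
#' BMIz for individual i is the sum of the specified SNP main effects
#' (effect x dosage), food main effects (effect x weekly frequency), SNP x
#' food interaction effects (effect x dosage x weekly frequency) and
#' covariate effects, plus Normal(0, noiseSd) noise. Missing dosages
#' contribute 0 to the genetic sums. A companion `bmi` column is derived by
#' inverting the LMS reference so the z-score machinery can be exercised on
#' the same data.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param cohort data.frame with `weekly_<item>` columns already present
#'   (see [addWeeklyFfq()]) and any covariates named in the spec.
#' @param spec an [effectSpec()].
#' @param lmsRef LMS reference for deriving the companion `bmi` column;
#'   NULL skips it.
#' @return The cohort with `bmiz` (and optionally `bmi`) columns filled.
#' @export
simulateBmiz <- function(genotypes, cohort, spec,
                         lmsRef = syntheticLmsReference()) {
  stopifnot(inherits(spec, "EffectSpec"))
  d <- dosage(genotypes)
  if (!identical(rownames(d), cohort$id)) {
    stop("genotypes and cohort must share an identical ordered individual-ID list",
      call. = FALSE
    )
  }
  n <- nrow(cohort)
  weekly_cols <- grep("^weekly_", names(cohort), value = TRUE)
  if (length(weekly_cols) == 0) {
    stop("cohort has no weekly_<item> columns; recode the FFQ first", call. = FALSE)
  }
  d0 <- ifelse(is.na(d), 0, d)
  y <- numeric(n)
  for (rs in names(spec$snpMainEffects)) {
    if (!rs %in% colnames(d)) {
      stop("effect spec references SNP absent from genotypes: ", rs, call. = FALSE)
    }
    y <- y + spec$snpMainEffects[[rs]] * d0[, rs]
  }
  for (food in names(spec$foodMainEffects)) {
    y <- y + spec$foodMainEffects[[food]] * .foodColumn(cohort, food)
  }
  if (!is.null(spec$interactionEffects)) {
    for (k in seq_len(nrow(spec$interactionEffects))) {
      rs <- spec$interactionEffects$rsid[k]
      food <- spec$interactionEffects$food[k]
      if (!rs %in% colnames(d)) {
        stop("effect spec references SNP absent from genotypes: ", rs, call. = FALSE)
      }
      y <- y + spec$interactionEffects$effect[k] *
        d0[, rs] * .foodColumn(cohort, food)
    }
  }
  for (cv in names(spec$covariateEffects)) {
    if (!cv %in% names(cohort)) {
      stop("effect spec references covariate absent from cohort: ", cv, call. = FALSE)
    }
    x <- cohort[[cv]]
    if (is.factor(x)) x <- as.numeric(x) - 1
    y <- y + spec$covariateEffects[[cv]] * x
  }
  set.seed(.subSeeds(spec$seed, 4)[4])
  cohort$bmiz <- y + rnorm(n, 0, spec$noiseSd)
  if (!is.null(lmsRef)) {
    cohort$bmi <- bmiFromZscore(cohort$bmiz, cohort$age, cohort$sex, lmsRef)
  }
  cohort
}

#' Simulate a complete study with known ground truth
#'
#' Convenience wrapper: genotypes ([simulateGenotypes()]), covariates and FFQ
#' ([simulateCohort()]), weekly recoding ([addWeeklyFfq()]) and BMIz
#' ([simulateBmiz()]), with per-stage sub-seeds derived from the spec's
#' master seed.
#'
#' @param n cohort size.
#' @param panel a [SNPPanel-class].
#' @param spec an [effectSpec()]; its `seed` drives every stage.
#' @param freqs risk-allele frequencies, see [simulateGenotypes()].
#' @param missingRate genotype missingness rate.
#' @param ffqMissingRate FFQ missingness rate.
#' @return A list with `genotypes`, `cohort` (BMIz filled) and `truth`
#'   (the spec).
#' @export
simulateStudy <- function(n, panel = defaultPanel(),
                          spec = effectSpec(noiseSd = 1, seed = 1L),
                          freqs = defaultRiskAlleleFreqs(panel),
                          missingRate = 0, ffqMissingRate = 0) {
  seeds <- .subSeeds(spec$seed, 4)
  genotypes <- simulateGenotypes(panel, n, freqs, missingRate, seed = seeds[1])
  cohort <- simulateCohort(n,
    seed = seeds[2],
    ffqMissingRate = ffqMissingRate
  )
  cohort <- addWeeklyFfq(cohort)
  cohort <- simulateBmiz(genotypes, cohort, spec)
  list(genotypes = genotypes, cohort = cohort, truth = spec)
}
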