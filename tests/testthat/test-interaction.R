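test_that("a noiseless interaction is recovered exactly", {
  set.seed(1)
  g <- rbinom(100, 2, 0.5)
  e <- runif(100, 0, 14)
  y <- 1 + 0.5 * g + 0.2 * e + 0.08 * g * e
  fit <- fitInteraction(y, g, e)
  expect_equal(fit$b[fit$term == "interaction"], 0.08, tolerance = 1e-8)
  expect_lt(fit$p[fit$term == "interaction"], 1e-12)
  expect_equal(fit$b[fit$term == "score"], 0.5, tolerance = 1e-8)
})

test_that("coefficients, SEs, t, p and CIs match the normal-equations oracle", {
  set.seed(30)
  n <- 30
  g <- rbinom(n, 2, 0.4)
  e <- runif(n, 0, 10)
  covs <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  y <- 0.3 * g - 0.1 * e + 0.05 * g * e + 0.2 * covs$c1 + rnorm(n)
  fit <- fitInteraction(y, g, e, covs)
  X <- cbind(1, g, e, covs$c1, covs$c2, g * e)
  oracle <- olsOracle(y, X)
  expect_equal(fit$b, oracle$b, tolerance = 1e-8)
  expect_equal(fit$se, oracle$se, tolerance = 1e-8)
  expect_equal(fit$t, oracle$b / oracle$se, tolerance = 1e-8)
  expect_equal(fit$p, 2 * pt(-abs(oracle$b / oracle$se), oracle$df), tolerance = 1e-8)
  tcrit <- qt(0.975, oracle$df)
  expect_equal(fit$ci_low, oracle$b - tcrit * oracle$se, tolerance = 1e-8)
  expect_equal(fit$ci_high, oracle$b + tcrit * oracle$se, tolerance = 1e-8)
  # standardized beta = b * sd(term)/sd(y), product term standardized as itself
  expect_equal(
    fit$beta[fit$term == "interaction"],
    fit$b[fit$term == "interaction"] * sd(g * e) / sd(y)
  )
  expect_true(all(fit$ci_low <= fit$b & fit$b <= fit$ci_high))
})

test_that("complete-case handling, factor covariates and error paths work", {
  set.seed(12)
  n <- 60
  g <- rbinom(n, 2, 0.5)
  e <- runif(n, 0, 5)
  sexf <- factor(sample(c("girl", "boy"), n, replace = TRUE))
  y <- 0.2 * g + 0.1 * e + rnorm(n)
  e[1:5] <- NA
  fit <- fitInteraction(y, g, e, data.frame(sex = sexf))
  expect_equal(unique(fit$n_used), 55)
  # constant predictor
  expect_error(fitInteraction(y, rep(1, n), e), "constant")
  # rank deficiency names the offending term
  covs <- data.frame(dup = g)
  expect_error(fitInteraction(y, g, e, covs), "singular|dup")
  # insufficient n
  expect_error(fitInteraction(y[1:8], g[1:8], e[6:13]), "insufficient")
})

test_that("the interaction test attains its nominal type-I error under the null", {
  set.seed(2024)
  n <- 1000
  reps <- 1000
  hits <- 0L
  for (r in seq_len(reps)) {
    g <- rbinom(n, 2, 0.45)
    e <- runif(n, 0, 14)
    y <- 0.1 * g + 0.05 * e + rnorm(n)
    fit <- fitInteraction(y, g, e)
    hits <- hits + (fit$p[fit$term == "interaction"] < 0.05)
  }
  expect_gte(hits / reps, 0.035)
  expect_lte(hits / reps, 0.065)
})

test_that("the whole-GRS screen flags a strongly interacting food and uses the borderline band", {
  panel <- makePanel(10)
  spec <- effectSpec(
    interactionEffects = data.frame(
      rsid = rsids(panel)[1:5], food = "pizza", effect = 0.12,
      stringsAsFactors = FALSE
    ),
    noiseSd = 1, seed = 31
  )
  study <- simulateStudy(1142, panel, spec)
  res <- screenWholeGrs(study$cohort, study$genotypes, panel,
    foods = c("pizza", "water"), schemes = c("unweighted", "speliotes")
  )
  expect_true("pizza" %in% res$flagged)
  expect_equal(res$referenceDirections[["pizza"]], 1)
  # dichotomized p is only filled inside the borderline band
  rep <- res$report
  filled <- !is.na(rep$p_dichotomized)
  expect_true(all(rep$p_continuous[filled] >= 0.15 & rep$p_continuous[filled] < 0.25))
})

test_that("the flag rule reproduces itself on constructed p-value tables", {
  tab <- data.frame(
    food = c("a", "a", "b", "b", "c"),
    p_continuous = c(0.5, 0.149, 0.2, 0.16, 0.9),
    p_dichotomized = c(NA, NA, NA, 0.12, NA)
  )
  expect_equal(applyFlagRule(tab), c("a", "b"))
  expect_equal(applyFlagRule(tab, alpha = 0.05), character(0))
})

test_that("per-SNP screening selects planted SNPs and respects the direction filter", {
  panel <- makePanel(30)
  truth_snps <- c("rs003", "rs011", "rs027")
  spec <- effectSpec(
    interactionEffects = data.frame(
      rsid = truth_snps, food = "pizza", effect = 0.1,
      stringsAsFactors = FALSE
    ),
    noiseSd = 1, seed = 55
  )
  study <- simulateStudy(5000, panel, spec)
  sel <- screenSnps(study$cohort, study$genotypes, panel, "pizza",
    referenceDirection = 1
  )
  expect_true(all(truth_snps %in% sel$selected))
  # selection preserves panel order
  expect_identical(sel$selected, rsids(panel)[rsids(panel) %in% sel$selected])
  # flipping the reference direction yields the complementary-signed subset
  sel_flip <- screenSnps(study$cohort, study$genotypes, panel, "pizza",
    referenceDirection = -1
  )
  both <- intersect(sel$selected, sel_flip$selected)
  expect_length(both, 0)
  res <- sel$results
  expect_identical(
    sort(c(sel$selected, sel_flip$selected)),
    sort(res$rsid[res$p < 0.2 & res$b != 0])
  )
})

test_that("building a food-specific GRS validates its inputs", {
  panel <- makePanel(5)
  fg <- buildFoodGrs(panel, c("rs004", "rs001"), "pizza", 1)
  expect_s4_class(fg, "FoodGRS")
  expect_equal(rsids(fg), c("rs001", "rs004")) # panel order imposed
  expect_error(buildFoodGrs(panel, character(0), "pizza", 1), "empty")
  expect_error(buildFoodGrs(panel, c("rs001", "rs001"), "pizza", 1), "duplicated")
  expect_error(buildFoodGrs(panel, "rsX", "pizza", 1), "rsX")
  # whole-panel subset scores identically to the whole unweighted GRS
  g <- simulateGenotypes(panel, 50, setNames(rep(0.5, 5), rsids(panel)), seed = 1)
  fg_all <- buildFoodGrs(panel, rsids(panel), "pizza", 1)
  expect_equal(
    scores(subsetScore(g, panel, rsids(fg_all))),
    scores(grsScore(g, panel, "unweighted"))
  )
})

test_that("validation models recover a planted aggregate interaction and covariates matter little when null", {
  panel <- makePanel(12)
  subset_snps <- rsids(panel)[c(2, 5, 8, 11)]
  gamma <- 0.06
  spec <- effectSpec(
    interactionEffects = data.frame(
      rsid = subset_snps, food = "pizza", effect = gamma,
      stringsAsFactors = FALSE
    ),
    noiseSd = 1, seed = 9
  )
  study <- simulateStudy(1142, panel, spec)
  fg <- buildFoodGrs(panel, subset_snps, "pizza", 1)
  v <- validateFoodGrs(study$cohort, study$genotypes, panel, fg)
  expect_named(v, c("model1", "model2"))
  for (m in v) {
    expect_setequal(m$term, c("score", "pizza", "interaction"))
  }
  int2 <- v$model2[v$model2$term == "interaction", ]
  expect_lt(int2$ci_low, gamma)
  expect_gt(int2$ci_high, gamma)
  # LTPA and sleep are null here: model 1 vs model 2 interaction differs < 2 SE
  int1 <- v$model1[v$model1$term == "interaction", ]
  expect_lt(abs(int1$b - int2$b), 2 * int2$se)
  # degenerate food with zero variance -> singular/constant design error
  study$cohort$weekly_pizza <- 3
  expect_error(
    validateFoodGrs(study$cohort, study$genotypes, panel, fg),
    "constant|singular"
  )
})

test_that("stratified effects obey the dummy-coding algebra and degenerate cases", {
  panel <- makePanel(8)
  spec <- effectSpec(
    interactionEffects = data.frame(
      rsid = rsids(panel)[1:3], food = "pizza", effect = 0.1,
      stringsAsFactors = FALSE
    ),
    noiseSd = 1, seed = 41
  )
  study <- simulateStudy(800, panel, spec)
  fg <- buildFoodGrs(panel, rsids(panel)[1:3], "pizza", 1)
  # without covariates, b_high = b_food(joint) + b_interaction exactly
  s <- stratifiedEffects(study$cohort, study$genotypes, panel, fg,
    covariates = character(0)
  )
  joint <- fitInteraction(
    study$cohort$bmiz,
    as.numeric(dichotomize(subsetScore(study$genotypes, panel, rsids(fg)))$group[study$cohort$id] == "high"),
    study$cohort$weekly_pizza,
    gName = "grs_group", eName = "pizza"
  )
  b_food <- joint$b[joint$term == "pizza"]
  b_int <- joint$b[joint$term == "interaction"]
  expect_equal(s$by_group$b[s$by_group$group == "low"], b_food, tolerance = 1e-10)
  expect_equal(s$by_group$b[s$by_group$group == "high"], b_food + b_int,
    tolerance = 1e-10
  )
  expect_equal(s$interaction$b, b_int, tolerance = 1e-10)
  # tiny stratum -> domain error
  expect_error(
    stratifiedEffects(study$cohort[1:40, ], study$genotypes, panel, fg),
    "stratum"
  )
})

test_that("identical strata give equal effects and a null interaction", {
  panel <- makePanel(4)
  set.seed(6)
  n <- 200
  # construct genotypes so the dichotomized groups contain identical phenotype data
  d_low <- matrix(rbinom(n / 2 * 4, 1, 0.2), ncol = 4)
  d_high <- matrix(2, nrow = n / 2, ncol = 4)
  d <- rbind(d_low, d_high)
  colnames(d) <- rsids(panel)
  g <- makeGenotypes(d)
  cohort <- addWeeklyFfq(simulateCohort(n, seed = 6))
  cohort$id <- individualIds(g)
  half <- cohort[1:(n / 2), c("weekly_pizza")]
  y_half <- 0.3 * half + rnorm(n / 2)
  cohort$weekly_pizza <- c(half, half)
  cohort$bmiz <- c(y_half, y_half)
  fg <- buildFoodGrs(panel, rsids(panel), "pizza", 1)
  s <- stratifiedEffects(cohort, g, panel, fg,
    covariates = character(0), minPerGroup = 10
  )
  expect_equal(s$by_group$b[1], s$by_group$b[2], tolerance = 1e-10)
  expect_equal(s$interaction$b, 0, tolerance = 1e-10)
})

test_that("shared-SNP set algebra is exact, order-invariant and idempotent", {
  lists <- list(
    f1 = c("rs1", "rs2", "rs3"),
    f2 = c("rs2", "rs3", "rs4"),
    f3 = c("rs3", "rs5")
  )
  res <- sharedSnpAnalysis(lists)
  expect_setequal(res$union, paste0("rs", 1:5))
  expect_equal(res$intersection, "rs3")
  expect_equal(sum(res$regions$count), 5)
  expect_equal(
    res$regions$count[res$regions$region == "f1 & f2 & f3"], 1
  )
  # order-invariance
  res2 <- sharedSnpAnalysis(lists[c(3, 1, 2)])
  expect_setequal(res2$union, res$union)
  expect_setequal(res2$intersection, res$intersection)
  # single list: intersection = union = the list
  res1 <- sharedSnpAnalysis(lists[1])
  expect_equal(res1$union, lists$f1)
  expect_equal(res1$intersection, lists$f1)
  # idempotent under duplication of a whole set
  res3 <- sharedSnpAnalysis(c(lists, list(f1b = lists$f1)))
  expect_setequal(res3$union, res$union)
  expect_error(sharedSnpAnalysis(list(f = c("rs1", "rs1"))), "duplicated")
})
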