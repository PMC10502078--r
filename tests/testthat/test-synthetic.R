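test_that("genotype simulation follows the binomial expectation and is seeded", {
  panel <- makePanel(1)
  freqs <- setNames(0.4, rsids(panel))
  g <- simulateGenotypes(panel, 10000, freqs, seed = 13)
  m <- mean(dosage(g))
  se <- sqrt(2 * 0.4 * 0.6 / 10000)
  expect_lt(abs(m - 0.8), 3 * se)
  g2 <- simulateGenotypes(panel, 10000, freqs, seed = 13)
  expect_identical(dosage(g), dosage(g2))
  g3 <- simulateGenotypes(panel, 10000, freqs, seed = 14)
  expect_false(identical(dosage(g), dosage(g3)))
})

test_that("degenerate or mismatched genotype-simulation inputs are rejected", {
  panel <- makePanel(2)
  expect_error(
    simulateGenotypes(panel, 10, setNames(c(1.0, 0.5), rsids(panel))),
    "strictly inside"
  )
  expect_error(
    simulateGenotypes(panel, 10, setNames(c(0.4, 0.5), c("rs001", "rsX"))),
    "rsX"
  )
  expect_error(
    simulateGenotypes(panel, 10, setNames(0.4, "rs001")),
    "rs002"
  )
  expect_error(simulateGenotypes(panel, 0), "at least 1")
})

test_that("missingness is injected at the requested rate", {
  panel <- makePanel(10)
  g <- simulateGenotypes(panel, 2000,
    setNames(rep(0.5, 10), rsids(panel)),
    missingRate = 0.05, seed = 3
  )
  rate <- mean(is.na(dosage(g)))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
})

test_that("genotype frequencies satisfy Hardy-Weinberg goodness of fit in aggregate", {
  panel <- makePanel(100)
  freqs <- setNames(runif(100, 0.2, 0.8), rsids(panel))
  set.seed(1)
  freqs[] <- round(freqs, 3)
  g <- simulateGenotypes(panel, 10000, freqs, seed = 100)
  d <- dosage(g)
  pvals <- vapply(seq_len(100), function(j) {
    obs <- tabulate(d[, j] + 1, nbins = 3)
    p <- freqs[j]
    expd <- 10000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    sum_chi <- sum((obs - expd)^2 / expd)
    pchisq(sum_chi, df = 2, lower.tail = FALSE)
  }, numeric(1))
  # expect about 1 rejection at alpha = 0.01 over 100 SNPs; allow 5
  expect_lte(sum(pvals < 0.01), 5)
})

test_that("cohort covariates match their target distributions", {
  cohort <- simulateCohort(5000, seed = 17)
  expect_equal(nrow(cohort), 5000)
  expect_gt(mean(cohort$ltpa), 6.4)
  expect_lt(mean(cohort$ltpa), 7.0)
  expect_true(all(cohort$ltpa >= 0))
  expect_lt(abs(mean(cohort$sleep) - 9.8), 3 * 0.7 / sqrt(5000))
  expect_lt(abs(mean(cohort$age) - 11.3), 3 * 0.2 / sqrt(5000))
  ratings <- as.matrix(cohort[, paste0("ffq_", ffqItems())])
  expect_true(all(ratings %in% 1:7))
  # weekly means land near the calibration targets
  weekly <- recodeFfq(cohort[, paste0("ffq_", ffqItems())])
  means <- colMeans(weekly)
  targets <- defaultFfqWeeklyMeans()
  expect_lt(max(abs(means - targets)), 0.35)
})

test_that("the smallest cohort is a single complete row", {
  cohort <- simulateCohort(1, seed = 2)
  expect_equal(nrow(cohort), 1)
  expect_false(anyNA(cohort))
})

test_that("FFQ missingness is supported and off by default", {
  c0 <- simulateCohort(500, seed = 3)
  expect_false(anyNA(c0))
  c1 <- simulateCohort(500, seed = 3, ffqMissingRate = 0.1)
  ratings <- as.matrix(c1[, paste0("ffq_", ffqItems())])
  expect_gt(mean(is.na(ratings)), 0.05)
  expect_lt(mean(is.na(ratings)), 0.15)
})

test_that("BMIz generation reproduces the linear ground truth", {
  panel <- makePanel(5)
  spec0 <- effectSpec(noiseSd = 1e-12, seed = 5)
  study <- simulateStudy(100, panel, spec0)
  # all effects zero, vanishing noise -> BMIz ~ 0
  expect_lt(max(abs(study$cohort$bmiz)), 1e-9)

  # single SNP main effect 0.5: dosage-2 minus dosage-0 individuals differ by 1
  spec1 <- effectSpec(
    snpMainEffects = c(rs003 = 0.5),
    noiseSd = 1e-12, seed = 5
  )
  study1 <- simulateStudy(400, panel, spec1)
  d <- dosage(study1$genotypes)[, "rs003"]
  y <- study1$cohort$bmiz
  expect_equal(
    mean(y[d == 2]) - mean(y[d == 0]), 1.0,
    tolerance = 1e-8
  )
})

test_that("missing dosages contribute zero to the generated outcome", {
  panel <- makePanel(2)
  d <- matrix(c(NA, 2, 1, 1), nrow = 2,
    dimnames = list(c("id0001", "id0002"), rsids(panel))
  )
  g <- makeGenotypes(d)
  cohort <- addWeeklyFfq(simulateCohort(2, seed = 4))
  spec <- effectSpec(
    snpMainEffects = c(rs001 = 10),
    noiseSd = 1e-12, seed = 4
  )
  out <- simulateBmiz(g, cohort, spec, lmsRef = NULL)
  expect_lt(abs(out$bmiz[1]), 1e-9) # NA dosage -> no contribution
  expect_equal(out$bmiz[2], 10 * d["id0002", "rs001"], tolerance = 1e-6)
})

test_that("effect specs referencing unknown SNPs, foods or covariates fail", {
  panel <- makePanel(2)
  study <- simulateStudy(20, panel)
  expect_error(
    simulateBmiz(study$genotypes, study$cohort,
      effectSpec(snpMainEffects = c(rsZZZ = 1), noiseSd = 1),
      lmsRef = NULL
    ),
    "rsZZZ"
  )
  expect_error(effectSpec(foodMainEffects = c(cake = 1), noiseSd = 1), "cake")
  expect_error(effectSpec(noiseSd = 0), "positive")
  expect_error(
    simulateBmiz(study$genotypes, study$cohort,
      effectSpec(covariateEffects = c(nope = 1), noiseSd = 1),
      lmsRef = NULL
    ),
    "nope"
  )
})

test_that("the null-model BMIz has the specified mean and SD at large n", {
  panel <- makePanel(3)
  spec <- effectSpec(noiseSd = 0.8, seed = 77)
  study <- simulateStudy(5000, panel, spec)
  y <- study$cohort$bmiz
  expect_lt(abs(mean(y)), 3 * 0.8 / sqrt(5000))
  expect_lt(abs(sd(y) - 0.8) / 0.8, 0.05)
})

test_that("whole studies are reproducible from the master seed", {
  panel <- makePanel(4)
  s1 <- simulateStudy(50, panel, effectSpec(noiseSd = 1, seed = 123))
  s2 <- simulateStudy(50, panel, effectSpec(noiseSd = 1, seed = 123))
  expect_identical(dosage(s1$genotypes), dosage(s2$genotypes))
  expect_identical(s1$cohort, s2$cohort)
  # genotypes and cohort share an identical ordered individual-ID list
  expect_identical(individualIds(s1$genotypes), s1$cohort$id)
})
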