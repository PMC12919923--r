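test_that("null-trait p-values are uniform", {
  cfg <- simulationConfig(nSnpsExposure = 1000, nMediators = 0,
                          nSnpsMediator = 0)
  set.seed(21)
  g <- simulateGenotypes(cfg, n = 2000)
  y <- rnorm(2000)
  ss <- computeSummaryStats(g$genotypes, y, g$panel, "continuous")
  frac <- mean(ss@data$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("chi-square at a causal variant matches the non-centrality closed form", {
  # one variant explaining r2 = 0.01 at n = 50,000: E[chi2] ~ n r2 = 500
  cfg <- simulationConfig(nSnpsExposure = 1, nMediators = 0,
                          nSnpsMediator = 0)
  set.seed(500)
  n <- 50000
  g <- simulateGenotypes(cfg, n = n)
  gv <- g$genotypes[, 1]
  b <- sqrt(0.01 / var(gv))
  y <- b * gv + rnorm(n, sd = sqrt(0.99))
  ss <- computeSummaryStats(g$genotypes, y, g$panel, "continuous")
  chi2 <- (ss@data$beta / ss@data$standard_error)^2
  # noncentral chi-square(1, 500): sd = sqrt(2 + 4 * 500)
  expect_lt(abs(chi2 - 500), 3.5 * sqrt(2 + 4 * 500))
})

test_that("recoding the effect allele flips beta and leaves p unchanged", {
  cfg <- simulationConfig(nSnpsExposure = 10, nMediators = 0,
                          nSnpsMediator = 0)
  set.seed(4)
  g <- simulateGenotypes(cfg, n = 3000)
  y <- 0.05 * g$genotypes[, 1] + rnorm(3000)
  ss1 <- computeSummaryStats(g$genotypes, y, g$panel, "continuous")
  ss2 <- computeSummaryStats(2L - g$genotypes, y, g$panel, "continuous")
  expect_equal(ss2@data$beta, -ss1@data$beta, tolerance = 1e-10)
  expect_equal(ss2@data$p_value, ss1@data$p_value, tolerance = 1e-10)
})

test_that("batched logistic GWAS agrees with glm variant by variant", {
  cfg <- simulationConfig(nSnpsExposure = 6, nMediators = 0,
                          nSnpsMediator = 0)
  set.seed(11)
  g <- simulateGenotypes(cfg, n = 1500)
  lp <- -2 + 0.3 * g$genotypes[, 2]
  y <- rbinom(1500, 1, plogis(lp))
  ss <- computeSummaryStats(g$genotypes, y, g$panel, "binary")
  for (j in 1:6) {
    fit <- glm(y ~ g$genotypes[, j], family = binomial())
    expect_equal(ss@data$beta[j], unname(coef(fit)[2]), tolerance = 1e-5)
    expect_equal(ss@data$standard_error[j],
                 unname(summary(fit)$coefficients[2, 2]),
                 tolerance = 1e-4)
  }
})

test_that("covariate-adjusted GWAS agrees with the full model fits", {
  cfg <- simulationConfig(nSnpsExposure = 4, nMediators = 0,
                          nSnpsMediator = 0)
  set.seed(12)
  n <- 1200
  g <- simulateGenotypes(cfg, n = n)
  covs <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- 0.1 * g$genotypes[, 1] + 0.5 * covs[, 1] + rnorm(n)
  ss <- computeSummaryStats(g$genotypes, y, g$panel, "continuous",
                            covariates = covs)
  fit <- lm(y ~ covs + g$genotypes[, 1])
  expect_equal(ss@data$beta[1], unname(coef(fit)[4]), tolerance = 1e-10)
  expect_equal(ss@data$standard_error[1],
               unname(summary(fit)$coefficients[4, 2]), tolerance = 1e-10)
  yb <- rbinom(n, 1, plogis(-1 + 0.3 * g$genotypes[, 2] + 0.4 * covs[, 1]))
  ssb <- computeSummaryStats(g$genotypes, yb, g$panel, "binary",
                             covariates = covs)
  fitb <- glm(yb ~ covs + g$genotypes[, 2], family = binomial())
  expect_equal(ssb@data$beta[2], unname(coef(fitb)[4]), tolerance = 1e-6)
})

test_that("monomorphic variants are flagged and skipped", {
  cfg <- simulationConfig(nSnpsExposure = 3, nMediators = 0,
                          nSnpsMediator = 0)
  set.seed(2)
  g <- simulateGenotypes(cfg, n = 300)
  g$genotypes[, 2] <- 0L
  expect_message(
    ss <- computeSummaryStats(g$genotypes, rnorm(300), g$panel,
                              "continuous"),
    "monomorphic")
  expect_equal(nrow(ss@data), 2L)
  expect_identical(attr(ss, "skipped"), g$panel$variant_id[2])
})

test_that("matched sets satisfy every constraint under a brute-force check", {
  cfg <- smallConfig(seed = 5)
  sim <- simulateStudy(cfg, components = "cohort")
  ncc <- buildNestedCaseControl(sim$cohort, ratio = 1,
                                tolerances = list(age = 2))
  sets <- split(seq_len(nrow(ncc)), ncc$matched_set)
  expect_true(all(lengths(sets) == 2L))
  nCases <- sum(sim$cohort$event)
  expect_lte(length(sets), nCases)
  # exhaustive constraint checker over every matched pair
  for (s in sets) {
    case <- ncc[s[ncc$event[s] == 1L], ]
    ctrl <- ncc[s[ncc$event[s] == 0L], ]
    expect_equal(nrow(case), 1L)
    expect_identical(ctrl$sex, case$sex)
    expect_lte(abs(ctrl$age - case$age), 2)
    # incidence density: control still at risk at the case's event time
    orig <- sim$cohort[match(ctrl$id, sim$cohort$id), ]
    expect_gt(orig$followup_time, case$followup_time)
  }
  # controls are sampled without replacement
  ctrlIds <- ncc$id[ncc$event == 0L]
  expect_false(anyDuplicated(ctrlIds) > 0)
})

test_that("an infeasible matching tolerance yields no pairs", {
  cohort <- data.frame(
    id = paste0("p", 1:6),
    age = c(1.1, 2.2, 3.3, 4.4, 5.5, 6.6),
    sex = rep(0L, 6),
    followup_time = c(1, 2, 3, 4, 5, 6),
    event = c(1L, 0L, 1L, 0L, 0L, 0L))
  expect_warning(
    ncc <- buildNestedCaseControl(cohort, tolerances = list(age = 0)),
    "no eligible control")
  expect_equal(nrow(ncc), 0L)
  expect_length(attr(ncc, "unmatched"), 2L)
})
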