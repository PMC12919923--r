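test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(nIndividuals = -5), "positive")
  expect_error(simulationConfig(ldRho = 1), "ldRho")
  expect_error(simulationConfig(mafRange = c(0.001, 0.5)), "mafRange")
  expect_error(simulationConfig(h2Exposure = 0.9,
                                confounderStrength = 0.5),
               "variance budget")
  expect_s4_class(simulationConfig(), "SimulationConfig")
})

test_that("independent variants are uncorrelated and HWE holds", {
  cfg <- simulationConfig(nSnpsExposure = 12, nMediators = 0,
                          nSnpsMediator = 0, ldRho = 0,
                          mafRange = c(0.5, 0.5))
  set.seed(42)
  n <- 10000
  g <- simulateGenotypes(cfg, n = n)$genotypes
  # HWE symmetry at maf 0.5: genotype frequencies (0.25, 0.5, 0.25)
  freq <- table(factor(g[, 1], levels = 0:2)) / n
  se3 <- 3 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(freq[["0"]] - 0.25), se3)
  expect_lt(abs(freq[["2"]] - 0.25), se3)
  expect_lt(abs(freq[["1"]] - 0.5), 3 * sqrt(0.5 * 0.5 / n))
  # independence: off-diagonal correlations within 3/sqrt(n) of zero
  cc <- cor(g)
  offDiag <- cc[upper.tri(cc)]
  expect_lt(max(abs(offDiag)), 3 / sqrt(n))
})

test_that("allele frequencies respect the configured range", {
  cfg <- simulationConfig(nSnpsExposure = 30, nMediators = 0,
                          nSnpsMediator = 0, mafRange = c(0.1, 0.4))
  set.seed(7)
  sim <- simulateGenotypes(cfg, n = 20000)
  eaf <- colMeans(sim$genotypes) / 2
  expect_true(all(abs(eaf - sim$panel$maf) < 3 * sqrt(0.25 / 20000) * 2))
  expect_true(all(sim$panel$maf >= 0.1 & sim$panel$maf <= 0.4))
})

test_that("LD blocks reproduce the target adjacent genotype correlation", {
  cfg <- simulationConfig(nSnpsExposure = 20, nMediators = 0,
                          nSnpsMediator = 0, ldBlockSize = 5,
                          ldRho = 0.8)
  set.seed(9)
  n <- 40000
  sim <- simulateGenotypes(cfg, n = n)
  g <- sim$genotypes
  panel <- sim$panel
  # brute-force pairwise-correlation oracle over adjacent pairs
  r2adj <- c()
  r2cross <- c()
  for (i in seq_len(ncol(g) - 1)) {
    r <- sum((g[, i] - mean(g[, i])) * (g[, i + 1] - mean(g[, i + 1]))) /
      sqrt(sum((g[, i] - mean(g[, i]))^2) *
             sum((g[, i + 1] - mean(g[, i + 1]))^2))
    if (panel$block[i] == panel$block[i + 1]) {
      r2adj <- c(r2adj, r^2)
    } else {
      r2cross <- c(r2cross, r^2)
    }
  }
  expect_equal(mean(r2adj), 0.64, tolerance = 0.03)
  expect_lt(max(r2cross), (3 / sqrt(n))^2 * 4)
})

test_that("null world has the closed-form event rate and zero estimands", {
  cfg <- simulationConfig(nIndividuals = 30000, nSnpsExposure = 5,
                          nMediators = 1, nSnpsMediator = 3,
                          betaXM = 0, betaMY = 0, betaXYdirect = 0,
                          confounderStrength = 0, ageEffectExposure = 0,
                          ageEffectHazard = 0, sexEffectHazard = 0,
                          baselineHazard = 2e-3)
  set.seed(5)
  g <- simulateGenotypes(cfg, n = cfg@nIndividuals)
  sim <- simulateTraits(g$genotypes, g$panel, cfg)
  pExp <- 1 - exp(-cfg@baselineHazard * cfg@followupYears)
  rate <- mean(sim$cohort$event)
  expect_lt(abs(rate - pExp), 4 * sqrt(pExp * (1 - pExp) / 30000))
  expect_equal(sim$groundTruth@totalLogEffect, 0)
  expect_equal(sim$groundTruth@indirectLogEffect, 0)
})

test_that("ground truth follows the stated DAG arithmetic", {
  cfg <- simulationConfig(betaXM = 0.5, betaMY = 0.4, betaXYdirect = 0.2)
  gt <- groundTruth(cfg)
  expect_equal(gt@indirectLogEffect, 0.20)
  expect_equal(gt@totalLogEffect, 0.40)
  expect_equal(gt@proportionMediated, 0.50)
  expect_equal(gt@totalLogEffect,
               gt@directLogEffect + sum(gt@indirectLogEffect))
})

test_that("ground truth matches a numerical do-intervention oracle", {
  cfg <- simulationConfig(nMediators = 2, betaXM = c(0.5, 0.3),
                          betaMY = c(0.4, 0.2), betaMM = 0.25,
                          betaXYdirect = 0.15)
  gt <- groundTruth(cfg)
  # oracle: finite-difference of the expected log-hazard under do(X = x),
  # propagating the structural equations with common random numbers
  set.seed(31)
  nmc <- 2e5
  U <- rnorm(nmc)
  e1 <- rnorm(nmc); e2 <- rnorm(nmc)
  cs <- cfg@confounderStrength
  lpAt <- function(x) {
    m1 <- cfg@betaXM[1] * x + cs * U + sqrt(1 - cs^2) * e1
    m2 <- cfg@betaXM[2] * x + cfg@betaMM * m1 + cs * U +
      sqrt(1 - cs^2) * e2
    mean(cfg@betaXYdirect * x + cfg@betaMY[1] * m1 + cfg@betaMY[2] * m2)
  }
  totalNum <- (lpAt(1) - lpAt(-1)) / 2
  expect_equal(totalNum, gt@totalLogEffect, tolerance = 0.01)
})

test_that("the default world yields the expected event count at scale", {
  cfg <- simulationConfig()
  set.seed(1402)
  g <- simulateGenotypes(cfg, n = 1e5)
  sim <- simulateTraits(g$genotypes, g$panel, cfg)
  # Poisson-count oracle around the calibrated target of ~1,400 events
  expect_lt(abs(sum(sim$cohort$event) - 1400), 4 * sqrt(1400))
})

test_that("identical config and seed reproduce identical studies with disjoint arms", {
  cfg <- smallConfig(seed = 77)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$sumstats$exposure@data, s2$sumstats$exposure@data)
  expect_identical(s1$sumstats$outcome@data, s2$sumstats$outcome@data)
  # two-sample independence: arm identifiers are disjoint by construction
  expect_length(intersect(s1$cohort$id, paste0("A", 1:6000)), 0)
})

test_that("baseline-hazard calibration hits its target", {
  cfg <- simulationConfig(nIndividuals = 20000)
  set.seed(3)
  g <- simulateGenotypes(cfg, n = 20000)
  sim <- simulateTraits(g$genotypes, g$panel, cfg)
  h0 <- calibrateBaselineHazard(cfg, targetEvents = 500, n = 20000,
                                linearPredictor = sim$linearPredictor)
  expected <- sum(1 - exp(-h0 * cfg@followupYears *
                            exp(sim$linearPredictor)))
  expect_equal(expected, 500, tolerance = 1e-6)
})
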