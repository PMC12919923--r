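test_that("a null a path gives a zero indirect effect with the right Sobel se", {
  a <- makeEffect(0, 0.02, scale = "linear")
  b <- makeEffect(0.3, 0.1, scale = "log_hazard")
  res <- productIndirect(a, b)
  expect_equal(res$indirect, 0)
  expect_equal(res$se, abs(0.3) * 0.02)
  expect_error(productIndirect(b, b), "linear")
  expect_error(productIndirect(a, makeEffect(1, 0.1, scale = "linear")),
               "log-risk")
})

test_that("Sobel uncertainty matches a million-draw product oracle", {
  # magnitudes anchored to the printed cohort insulin pathway
  a <- makeEffect(0.35, 0.02, scale = "linear")
  b <- makeEffect(log(1.38), 0.17, scale = "log_hazard")
  res <- productIndirect(a, b, nMc = 1e6, mcSeed = 5)
  set.seed(123)
  draws <- rnorm(1e6, 0.35, 0.02) * rnorm(1e6, log(1.38), 0.17)
  expect_equal(res$indirect, mean(draws), tolerance = 0.01)
  expect_equal(res$se, sd(draws), tolerance = 0.02)
  expect_equal(res$ci[1], quantile(draws, 0.025)[[1]], tolerance = 0.05)
  expect_equal(res$ci[2], quantile(draws, 0.975)[[1]], tolerance = 0.05)
  expect_equal(res$mcCi, unname(quantile(draws, c(0.025, 0.975))),
               tolerance = 0.02)
})

test_that("the cohort insulin pathway lands near the printed indirect effect", {
  # plausibility check only: the exposure-adjusted b path behind the
  # printed value is not public, so magnitudes, not equality
  a <- makeEffect(0.35, 0.02, scale = "linear")
  b <- makeEffect(log(1.38), 0.17, scale = "log_hazard")
  res <- productIndirect(a, b)
  expect_gt(exp(res$indirect), 1.05)
  expect_lt(exp(res$indirect), 1.20)
  expect_gt(exp(res$ci[1]), 0.98)
  expect_lt(exp(res$ci[2]), 1.35)
})

test_that("proportion mediated follows its arithmetic and flags range", {
  tot <- makeEffect(0.4, 0.05, scale = "log_hazard")
  pm <- proportionMediated(0.1, 0.03, tot)
  expect_equal(pm$pm, 0.25)
  expect_false(pm$outOfRange)
  expect_equal(proportionMediated(0.4, 0.03, tot)$pm, 1)
  over <- proportionMediated(0.6, 0.03, tot)
  expect_equal(over$pm, 1.5)        # reported verbatim
  expect_true(over$outOfRange)
  expect_error(proportionMediated(0.1, 0.03,
                                  makeEffect(0, 0.05, "log_hazard")),
               "nonzero")
  expect_error(proportionMediated(0.1, 0.03,
                                  makeEffect(1, 0.1, "linear")),
               "log-risk")
})

test_that("the delta-method pm interval matches a Monte-Carlo ratio oracle", {
  tot <- makeEffect(0.4, 0.04, scale = "log_hazard")
  pm <- proportionMediated(0.1, 0.02, tot)
  set.seed(9)
  draws <- rnorm(1e6, 0.1, 0.02) / rnorm(1e6, 0.4, 0.04)
  expect_equal(pm$ci[1], quantile(draws, 0.025)[[1]], tolerance = 0.05)
  expect_equal(pm$ci[2], quantile(draws, 0.975)[[1]], tolerance = 0.05)
})

test_that("cohort mediation assembles consistent components", {
  cfg <- simulationConfig(nIndividuals = 15000, nSnpsExposure = 8,
                          nSnpsMediator = 6, baselineHazard = 6e-3,
                          confounderStrength = 0, seed = 41)
  sim <- simulateStudy(cfg, components = "cohort")
  res <- mediateCohort(sim$cohort, "med1")
  expect_s4_class(res, "MediationResult")
  expect_identical(res@framework, "cohort")
  # indirect is exactly the stored a x b product
  expect_equal(res@indirectBeta, res@aPath@estimate * res@bPath@estimate)
  # sign algebra
  expect_equal(sign(res@indirectBeta),
               sign(res@aPath@estimate) * sign(res@bPath@estimate))
  # difference-method direct vs adjusted-coefficient direct are both there
  expect_equal(res@directDifference,
               res@total@estimate - res@indirectBeta)
  expect_equal(res@directAdjusted@estimate, res@total@estimate -
                 res@indirectBeta, tolerance = 0.25)
})

test_that("MR mediation suppresses the estimate under weak conditional F", {
  cfg <- smallConfig(seed = 43)
  sim <- simulateStudy(cfg)
  res <- mediateMR(sim$sumstats$exposure, sim$sumstats$mediators$med1,
                   sim$sumstats$outcome, ld = sim$ld,
                   weakFThreshold = 1e9, suppressWeak = TRUE)
  expect_true(res@weakInstrument)
  expect_true(is.na(res@proportionMediated))
  expect_match(paste(res@methodNotes, collapse = " "), "not calculated")
  res2 <- mediateMR(sim$sumstats$exposure, sim$sumstats$mediators$med1,
                    sim$sumstats$outcome, ld = sim$ld,
                    weakFThreshold = 10)
  expect_false(res2@weakInstrument)
  expect_false(is.na(res2@proportionMediated))
})

test_that("Sobel coverage of the indirect effect is near nominal", {
  # 2,000 synthetic replicates at moderate effects
  a0 <- 0.35; b0 <- 0.3
  seA <- 0.04; seB <- 0.06
  set.seed(2024)
  R <- 2000
  aHat <- rnorm(R, a0, seA)
  bHat <- rnorm(R, b0, seB)
  covered <- vapply(seq_len(R), function(r) {
    res <- productIndirect(makeEffect(aHat[r], seA, "linear"),
                           makeEffect(bHat[r], seB, "log_hazard"))
    res$ci[1] <= a0 * b0 && a0 * b0 <= res$ci[2]
  }, logical(1))
  cover <- mean(covered)
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})
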