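test_that("the Wald ratio follows its arithmetic and error cases", {
  w <- waldRatio(0.1, 0.01, 0.05, 0.01)
  expect_equal(w@estimate, 0.5)
  expect_equal(w@se, 0.1)
  expect_equal(waldRatio(0.1, 0.01, 0, 0.01)@estimate, 0)
  expect_error(waldRatio(0, 0.01, 0.05, 0.01), "nonzero")
})

test_that("the second-order Wald se matches a Monte-Carlo ratio oracle", {
  bx <- 1; sx <- 0.1; by <- 0.5; sy <- 0.1
  w <- waldRatio(bx, sx, by, sy, secondOrder = TRUE)
  set.seed(99)
  draws <- rnorm(1e6, by, sy) / rnorm(1e6, bx, sx)
  expect_equal(w@se, sd(draws), tolerance = 0.05)
  expect_gt(w@se, waldRatio(bx, sx, by, sy)@se)
})

test_that("homogeneous ratios give the common ratio with zero heterogeneity", {
  h <- makeHarmonized(bx = c(0.1, 0.2, 0.4), sx = rep(0.01, 3),
                      by = c(0.05, 0.1, 0.2), sy = rep(0.02, 3))
  est <- mrIvw(h)
  expect_equal(est@estimate, 0.5)
  expect_equal(est@qStatistic, 0)
})

test_that("IVW equals a weighted-least-squares-through-origin oracle", {
  set.seed(301)
  for (i in 1:25) {
    h <- randomHarmonized(sample(3:30, 1))
    fit <- lm(h@betaOutcome ~ 0 + h@betaExposure[, 1],
              weights = 1 / h@seOutcome^2)
    est <- mrIvw(h)
    expect_equal(est@estimate, unname(coef(fit)[1]), tolerance = 1e-10)
    # the lm se equals the fixed-effect se scaled by the model sigma;
    # the multiplicative random-effects se floors that scale at 1
    fixed <- mrIvw(h, "fixed")
    expect_equal(est@se, max(fixed@se,
                             unname(summary(fit)$coefficients[1, 2])),
                 tolerance = 1e-10)
    expect_gte(est@se, fixed@se)
  }
})

test_that("single-variant IVW degrades exactly to the Wald ratio", {
  h <- makeHarmonized(bx = 0.12, sx = 0.015, by = 0.03, sy = 0.02)
  expect_warning(est <- mrIvw(h), "Wald")
  w <- waldRatio(0.12, 0.015, 0.03, 0.02)
  expect_identical(est@estimate, w@estimate)
  expect_identical(est@se, w@se)
})

test_that("MR-Egger matches a weighted lm oracle and is shift-equivariant", {
  set.seed(55)
  h <- randomHarmonized(15)
  h@betaExposure[, 1] <- abs(h@betaExposure[, 1])
  eg <- mrEgger(h)
  fit <- lm(h@betaOutcome ~ h@betaExposure[, 1],
            weights = 1 / h@seOutcome^2)
  expect_equal(eg$slope@estimate, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(eg$intercept@estimate, unname(coef(fit)[1]),
               tolerance = 1e-10)
  # a constant pleiotropic offset moves the intercept, not the slope
  h2 <- h
  h2@betaOutcome <- h@betaOutcome + 0.03
  eg2 <- mrEgger(h2)
  expect_equal(eg2$slope@estimate, eg$slope@estimate, tolerance = 1e-10)
  expect_equal(eg2$intercept@estimate, eg$intercept@estimate + 0.03,
               tolerance = 1e-10)
  expect_error(mrEgger(makeHarmonized(0.1, 0.01, 0, 0.02)), "at least 3")
})

test_that("Egger and IVW are invariant to harmonized allele recoding", {
  set.seed(77)
  h <- randomHarmonized(12)
  flip <- sample(c(-1, 1), 12, replace = TRUE)
  h2 <- h
  h2@betaExposure[, 1] <- h@betaExposure[, 1] * flip
  h2@betaOutcome <- h@betaOutcome * flip
  expect_equal(mrIvw(h2)@estimate, mrIvw(h)@estimate, tolerance = 1e-12)
  expect_equal(mrIvw(h2)@se, mrIvw(h)@se, tolerance = 1e-12)
  e1 <- mrEgger(h); e2 <- mrEgger(h2)
  expect_equal(e2$slope@estimate, e1$slope@estimate, tolerance = 1e-12)
  expect_equal(e2$intercept@estimate, e1$intercept@estimate,
               tolerance = 1e-12)
})

test_that("the Egger intercept test is calibrated under no pleiotropy", {
  set.seed(404)
  cover <- 0L
  R <- 1000
  for (r in seq_len(R)) {
    J <- 20
    bx <- abs(rnorm(J, 0.08, 0.02))
    sy <- runif(J, 0.02, 0.05)
    by <- 0.3 * bx + rnorm(J, 0, sy)
    h <- makeHarmonized(bx, rep(0.01, J), by, sy)
    ic <- mrEgger(h)$intercept
    cover <- cover + (abs(ic@estimate) <= qnorm(0.975) * ic@se)
  }
  expect_gte(cover / R, 0.93)
})

test_that("MR-PRESSO is deterministic under a seed and guards its inputs", {
  set.seed(13)
  h <- randomHarmonized(10)
  r1 <- mrPresso(h, nSim = 300, seed = 42)
  r2 <- mrPresso(h, nSim = 300, seed = 42)
  expect_identical(r1$globalP, r2$globalP)
  expect_identical(r1$outliers, r2$outliers)
  expect_error(mrPresso(h, nSim = 50, seed = 1), "at least 100")
  expect_error(mrPresso(makeHarmonized(rep(0.1, 3), rep(0.01, 3),
                                       rep(0, 3), rep(0.02, 3)),
                        nSim = 300, seed = 1), "at least 4")
  expect_error(mrPresso(h, nSim = 300), "seed")
})

test_that("a grossly displaced variant is flagged as a PRESSO outlier", {
  set.seed(21)
  h <- randomHarmonized(15, slope = 0.3)
  # ratio displaced by ten times its standard error
  h@betaOutcome[4] <- 0.3 * h@betaExposure[4, 1] + 10 * h@seOutcome[4]
  res <- mrPresso(h, nSim = 500, seed = 7)
  expect_true(h@variants$variant_id[4] %in% res$outliers)
  expect_lt(res$globalP, 0.05)
  expect_equal(droppedVariants(res$filtered)$reason, "presso_outlier")
})

test_that("the Steiger filter keeps forward variants and boundary ties", {
  # forward: much more variance explained in the exposure
  h <- makeHarmonized(bx = 0.1, sx = 0.01, by = 0.001, sy = 0.01)
  expect_length(steigerFilter(h)$removed, 0L)
  # equal variance on both sides is retained (strict inequality drops)
  h2 <- makeHarmonized(bx = 0.1, sx = 0.01, by = 0.1, sy = 0.01)
  expect_length(steigerFilter(h2)$removed, 0L)
  # reverse: outcome side clearly stronger
  h3 <- makeHarmonized(bx = 0.001, sx = 0.01, by = 0.1, sy = 0.01)
  st <- steigerFilter(h3)
  expect_equal(st$removed, "rs0001")
  expect_equal(droppedVariants(st$filtered)$reason, "steiger_reverse")
})

test_that("MVMR matches an explicit normal-equation oracle", {
  set.seed(61)
  J <- 6
  X <- cbind(a = rnorm(J, 0.1, 0.03), b = rnorm(J, 0.05, 0.02))
  sy <- runif(J, 0.02, 0.04)
  y <- X %*% c(0.4, -0.2) + rnorm(J, 0, sy)
  h <- makeHarmonized(X[, 1], rep(0.01, J), drop(y), sy)
  h@betaExposure <- X
  h@seExposure <- matrix(0.01, J, 2, dimnames = list(NULL, c("a", "b")))
  h@nExposure <- matrix(5e4, J, 2, dimnames = list(NULL, c("a", "b")))
  h@exposures <- c("a", "b")
  mv <- mrMvmr(h)
  W <- diag(1 / sy^2)
  oracle <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_equal(mv$a@estimate, unname(oracle[1, 1]), tolerance = 1e-10)
  expect_equal(mv$b@estimate, unname(oracle[2, 1]), tolerance = 1e-10)
})

test_that("a zero column reduces MVMR to the univariable IVW estimate", {
  set.seed(62)
  h <- randomHarmonized(10)
  h2 <- h
  h2@betaExposure <- cbind(x = h@betaExposure[, 1], z = rep(0, 10))
  h2@seExposure <- cbind(x = h@seExposure[, 1], z = rep(0.01, 10))
  h2@nExposure <- cbind(x = h@nExposure[, 1], z = rep(5e4, 10))
  h2@exposures <- c("x", "z")
  mv <- mrMvmr(h2)
  ivw <- mrIvw(h)
  expect_equal(mv$x@estimate, ivw@estimate, tolerance = 1e-8)
  expect_equal(mv$x@se, ivw@se, tolerance = 1e-8)
  expect_true(is.na(mv$z@estimate))
  expect_true(mv$z@weakInstrument)
})

test_that("the weak-instrument flag triggers exactly at conditional F 10", {
  set.seed(63)
  J <- 12
  x1 <- rnorm(J, 0.1, 0.03)
  sx <- rep(0.01, J)
  mk <- function(x2) {
    h <- makeHarmonized(x1, sx, 0.3 * x1 + rnorm(J, 0, 0.02),
                        rep(0.02, J))
    h@betaExposure <- cbind(a = x1, b = x2)
    h@seExposure <- matrix(0.01, J, 2, dimnames = list(NULL, c("a", "b")))
    h@nExposure <- matrix(5e4, J, 2, dimnames = list(NULL, c("a", "b")))
    h@exposures <- c("a", "b")
    h
  }
  # conditional F computed the same way the estimator defines it
  condF <- function(h, k) {
    others <- h@betaExposure[, -k, drop = FALSE]
    wk <- 1 / h@seExposure[, k]^2
    fit <- lm(h@betaExposure[, k] ~ 0 + others, weights = wk)
    sum(wk * resid(fit)^2) / (J - 2 + 1)
  }
  hStrong <- mk(rnorm(J, 0.1, 0.05))
  hWeak <- mk(x1 + rnorm(J, 0, 0.004))   # barely separable second exposure
  mvS <- mrMvmr(hStrong)
  mvW <- mrMvmr(hWeak)
  expect_equal(mvS$b@conditionalF, condF(hStrong, 2), tolerance = 1e-8)
  expect_identical(mvS$b@weakInstrument, mvS$b@conditionalF < 10)
  expect_identical(mvW$b@weakInstrument, mvW$b@conditionalF < 10)
  expect_true(mvW$b@weakInstrument)
  expect_false(mvS$b@weakInstrument)
})
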