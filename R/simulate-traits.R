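#' @include simulate-genotypes.R
NULL

#' Closed-form ground truth for a simulated world
#'
#' Computes the mediation estimands implied by a configuration, on the
#' log-hazard scale per SD of exposure. The total exposure-to-mediator
#' effect of mediator k accumulates the chain path through earlier
#' mediators; the per-mediator indirect effect is the product of that path
#' with the mediator's log-hazard effect, so that
#' total = direct + sum(indirect) holds exactly.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GroundTruth-class] object.
#' @export
groundTruth <- function(config) {
  K <- config@nMediators
  d <- numeric(K)
  for (k in seq_len(K)) {
    d[k] <- config@betaXM[k] + if (k > 1) config@betaMM * d[k - 1] else 0
  }
  indirect <- config@betaMY * d
  total <- config@betaXYdirect + sum(indirect)
  pm <- if (abs(total) > 0) indirect / total else rep(NA_real_, K)
  new("GroundTruth", totalLogEffect = total,
      directLogEffect = config@betaXYdirect,
      indirectLogEffect = indirect, proportionMediated = pm,
      mediatorNames = config@mediatorNames)
}

#' Theoretical first and second moments of the simulated traits
#'
#' Propagates the structural loadings through the independent sources
#' (genetic scores, latent confounder, age, sex, noise) to the exact
#' variances of exposure, mediators and the log-hazard linear predictor.
#' Used for calibrating the baseline hazard and for expressing ground
#' truth per SD of a mediator.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `varExposure`, `varMediator` (vector), `varLp`, and
#'   `covExposureMediator` (vector).
#' @export
traitMoments <- function(config) {
  K <- config@nMediators
  cs <- config@confounderStrength
  ## sources: scoreX, U, ageZ, sexC, eX, then (scoreM_k, eM_k) per mediator
  nSrc <- 5L + 2L * K
  srcVar <- c(config@h2Exposure, 1, 1, 0.25,
              1 - config@h2Exposure - cs^2 - config@ageEffectExposure^2,
              rep(c(config@h2Mediator, 1 - config@h2Mediator - cs^2), K))
  x <- numeric(nSrc)
  x[1] <- 1; x[2] <- cs; x[3] <- config@ageEffectExposure; x[5] <- 1
  mLoad <- matrix(0, K, nSrc)
  for (k in seq_len(K)) {
    load <- config@betaXM[k] * x
    if (k > 1) load <- load + config@betaMM * mLoad[k - 1, ]
    load[2] <- load[2] + cs
    load[5L + 2L * k - 1L] <- 1
    load[5L + 2L * k] <- 1
    mLoad[k, ] <- load
  }
  lp <- config@betaXYdirect * x + cs * (seq_len(nSrc) == 2) +
    config@ageEffectHazard * (seq_len(nSrc) == 3) +
    config@sexEffectHazard * (seq_len(nSrc) == 4)
  for (k in seq_len(K)) lp <- lp + config@betaMY[k] * mLoad[k, ]
  list(varExposure = sum(x^2 * srcVar),
       varMediator = if (K) drop(mLoad^2 %*% srcVar) else numeric(0),
       varLp = sum(lp^2 * srcVar),
       covExposureMediator = if (K) drop(mLoad %*% (x * srcVar))
                             else numeric(0))
}

#' Calibrate the baseline hazard to an expected event count
#'
#' Solves for the constant baseline hazard under which the expected number
#' of events over the administrative follow-up equals a target, either from
#' a realized linear predictor (exact) or from the configuration's
#' theoretical linear-predictor variance (normal approximation).
#'
#' @param config a [SimulationConfig-class].
#' @param targetEvents expected number of events.
#' @param n number of individuals (defaults to `nIndividuals`).
#' @param linearPredictor optional realized linear predictor; when supplied
#'   the expectation is taken over it instead of the normal approximation.
#' @return baseline hazard (events per person-year).
#' @export
calibrateBaselineHazard <- function(config, targetEvents,
                                    n = config@nIndividuals,
                                    linearPredictor = NULL) {
  Tf <- config@followupYears
  if (is.null(linearPredictor)) {
    v <- traitMoments(config)$varLp
    expected <- function(h0) {
      n * stats::integrate(function(z) {
        (1 - exp(-h0 * Tf * exp(sqrt(v) * z))) * stats::dnorm(z)
      }, -8, 8, rel.tol = 1e-9)$value
    }
  } else {
    n <- length(linearPredictor)
    elp <- exp(linearPredictor)
    expected <- function(h0) sum(1 - exp(-h0 * Tf * elp))
  }
  .stopIfNot(targetEvents > 0 && targetEvents < n,
             "targetEvents must lie between 0 and n")
  stats::uniroot(function(lh) expected(exp(lh)) - targetEvents,
                 lower = log(1e-10), upper = log(10), tol = 1e-10)$root |>
    exp()
}

#' Simulate traits, covariates and survival outcome
#'
#' Builds the cohort table from a genotype matrix under the configured
#' structural model: the exposure is the exposure genetic score plus
#' confounder, age and noise contributions summing to unit variance; each
#' mediator adds `betaXM` times the exposure to its own unit-variance
#' genetic-plus-confounder-plus-noise part; event times are exponential
#' with individual log-hazard
#' `betaXYdirect * exposure + sum(betaMY * mediator) + confounder and
#' covariate loadings`, censored administratively at `followupYears`.
#' Decorative lifestyle covariates (center, education, smoking, alcohol)
#' are generated for use in adjustment sets.
#'
#' @param genotypes integer genotype matrix from [simulateGenotypes()].
#' @param panel the matching variant panel.
#' @param config a [SimulationConfig-class].
#' @param idPrefix prefix for participant identifiers (arms must not
#'   overlap; see [simulateStudy()]).
#' @return list with `cohort` (a `data.frame`: id, age, sex, center,
#'   education, smoking, alcohol, bmi, one column per mediator,
#'   followup_time, event), `groundTruth`, `linearPredictor` and
#'   `confounder`.
#' @export
simulateTraits <- function(genotypes, panel, config, idPrefix = "id") {
  validObject(config)
  n <- nrow(genotypes)
  K <- config@nMediators
  cs <- config@confounderStrength
  ageZ <- stats::rnorm(n)
  age <- pmin(pmax(round(55 + 8 * ageZ), 40), 70)
  sex <- stats::rbinom(n, 1L, 0.5)
  U <- stats::rnorm(n)

  idxX <- which(panel$role == "exposure")
  scoreX <- drop((genotypes[, idxX, drop = FALSE] -
                    rep(2 * panel$maf[idxX], each = n)) %*%
                   panel$trueBeta[idxX])
  vEX <- 1 - config@h2Exposure - cs^2 - config@ageEffectExposure^2
  x <- scoreX + cs * U + config@ageEffectExposure * ageZ +
    stats::rnorm(n, sd = sqrt(vEX))

  med <- matrix(0, n, K,
                dimnames = list(NULL, config@mediatorNames))
  vEM <- 1 - config@h2Mediator - cs^2
  for (k in seq_len(K)) {
    idxM <- which(panel$role == config@mediatorNames[k])
    scoreM <- if (length(idxM)) {
      drop((genotypes[, idxM, drop = FALSE] -
              rep(2 * panel$maf[idxM], each = n)) %*% panel$trueBeta[idxM])
    } else {
      ## variance budget is kept whether or not the mediator has instruments
      stats::rnorm(n, sd = sqrt(config@h2Mediator))
    }
    med[, k] <- config@betaXM[k] * x +
      (if (k > 1) config@betaMM * med[, k - 1] else 0) +
      scoreM + cs * U + stats::rnorm(n, sd = sqrt(vEM))
  }

  lp <- config@betaXYdirect * x + cs * U +
    config@ageEffectHazard * ageZ +
    config@sexEffectHazard * (sex - 0.5)
  if (K) lp <- lp + drop(med %*% config@betaMY)
  tEvent <- stats::rexp(n) / (config@baselineHazard * exp(lp))
  event <- as.integer(tEvent <= config@followupYears)
  followup <- pmin(tEvent, config@followupYears)

  cohort <- data.frame(
    id = paste0(idPrefix, seq_len(n)),
    age = age, sex = sex,
    center = factor(sample(paste0("C", 1:10), n, replace = TRUE)),
    education = factor(sample(c("basic", "secondary", "vocational",
                                "degree"), n, replace = TRUE)),
    smoking = factor(sample(c("never", "former", "current"), n,
                            replace = TRUE, prob = c(0.55, 0.3, 0.15)),
                     levels = c("never", "former", "current")),
    alcohol = factor(sample(c("never", "former", "current"), n,
                            replace = TRUE, prob = c(0.1, 0.05, 0.85)),
                     levels = c("never", "former", "current")),
    bmi = x, stringsAsFactors = FALSE
  )
  for (k in seq_len(K)) cohort[[config@mediatorNames[k]]] <- med[, k]
  cohort$followup_time <- followup
  cohort$event <- event
  list(cohort = cohort, groundTruth = groundTruth(config),
       linearPredictor = lp, confounder = U)
}
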