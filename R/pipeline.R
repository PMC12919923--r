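#' @include report.R
NULL

#' Run the full triangulated mediation pipeline
#'
#' Executes the three analytical steps on a simulated study:
#' (1) exposure-to-mediator effects estimated in parallel in the cohort
#' (adjusted linear models) and MR (univariable IVW) arms;
#' (2) mediator-to-risk effects in both arms (adjusted Cox models;
#' IVW after the configured Steiger and MR-PRESSO filters, with the
#' MR-Egger intercept as the pleiotropy check), plus the total exposure
#' effect in both arms;
#' (3) the concordance gate, and — for eligible mediators only —
#' product-method mediation in each framework. With two or more mediators
#' the pairwise mediator-mediator edge table is added, and the squared
#' correlation between the arms' exposure-to-mediator betas is reported
#' as the cross-arm concordance summary.
#'
#' Any stage failure halts with a stage-tagged error message.
#'
#' @param config configuration list from [loadConfig()] /
#'   [defaultConfig()].
#' @param outDir optional output directory passed to [writeTables()].
#' @return a result bundle (list) with elements `config`, `simConfig`,
#'   `groundTruth`, `counts`, `apath`, `risk`, `triangulation`,
#'   `triangulationRecords`, `mediation`, `mediationResults`, `edges`,
#'   `armConcordanceR2`, `droppedVariants`, `eggerIntercepts`.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  simCfg <- simulationConfigFromList(config)
  sim <- stage("simulate", simulateStudy(simCfg))
  meds <- simCfg@mediatorNames
  covars <- config$cohort$covariates
  ic <- config$instruments
  mrCfg <- config$mr
  ld <- sim$ld
  cohort <- sim$cohort
  for (m in meds) {
    cohort[[m]] <- as.numeric(
      transformTrait(cohort[[m]], config$cohort$transform))
  }

  instrX <- stage("instruments", selectInstruments(
    sim$sumstats$exposure, ic$p_threshold, ld, ic$r2_threshold,
    ic$window_kb))
  refine <- function(h, seedOffset = 0L) {
    if (isTRUE(mrCfg$steiger)) {
      h <- steigerFilter(h)$filtered
    }
    if (isTRUE(mrCfg$presso) && nVariants(h) >= 4) {
      h <- mrPresso(h, nSim = mrCfg$presso_n_sim,
                    seed = config$seed + seedOffset,
                    alphaOutlier = mrCfg$presso_outlier_alpha)$filtered
    }
    h
  }

  ## stage 1: exposure -> mediator, both arms
  apRows <- list()
  for (m in meds) {
    a <- stage("apath-cohort", apathLinear(cohort, m, "bmi", covars))
    apRows[[length(apRows) + 1L]] <- .effectRow(a, "cohort", "apath",
                                                term = m)
    hA <- stage("apath-mr",
                harmonize(instrX, sim$sumstats$mediators[[m]],
                          ic$palindromic_window))
    mreA <- stage("apath-mr", suppressWarnings(mrIvw(hA, mrCfg$model)))
    row <- .mreRow(mreA, "mr", "apath", term = m)
    row$scale <- "linear"
    apRows[[length(apRows) + 1L]] <- row
  }
  apath <- do.call(rbind, apRows)

  ## stage 2: risk in both arms (+ total exposure effect)
  riskRows <- list()
  dropRows <- list()
  eggerIntercepts <- stats::setNames(rep(NA_real_, length(meds)), meds)
  alphaGate <- config$triangulation$alpha
  if (isTRUE(config$triangulation$bonferroni) && length(meds)) {
    alphaGate <- alphaGate / length(meds)
  }
  totalCohort <- stage("risk-cohort", coxRisk(cohort, "bmi", covars))
  riskRows[[1L]] <- .effectRow(totalCohort, "cohort", "total")
  hT <- stage("risk-mr", refine(harmonize(instrX, sim$sumstats$outcome,
                                          ic$palindromic_window), 1L))
  totalMr <- stage("risk-mr", suppressWarnings(mrIvw(hT, mrCfg$model)))
  riskRows[[2L]] <- .mreRow(totalMr, "mr", "total")
  .dropTab <- function(analysis, d) {
    data.frame(analysis = rep(analysis, nrow(d)), d,
               stringsAsFactors = FALSE)
  }
  dropRows[[1L]] <- .dropTab("bmi->outcome", hT@dropped)

  records <- list()
  cohortRisk <- list()
  mrRisk <- list()
  for (k in seq_along(meds)) {
    m <- meds[k]
    ce <- stage("risk-cohort", coxRisk(cohort, m, covars))
    cohortRisk[[m]] <- ce
    riskRows[[length(riskRows) + 1L]] <- .effectRow(ce, "cohort", "risk")
    instrM <- tryCatch(
      selectInstruments(sim$sumstats$mediators[[m]], ic$p_threshold, ld,
                        ic$r2_threshold, ic$window_kb),
      warning = function(w) NULL)
    if (is.null(instrM) || nVariants(instrM) == 0L) next
    hM <- stage("risk-mr",
                refine(harmonize(instrM, sim$sumstats$outcome,
                                 ic$palindromic_window), 1L + k))
    me <- stage("risk-mr", suppressWarnings(mrIvw(hM, mrCfg$model)))
    mrRisk[[m]] <- me
    riskRows[[length(riskRows) + 1L]] <- .mreRow(me, "mr", "risk")
    dropRows[[length(dropRows) + 1L]] <-
      .dropTab(sprintf("%s->outcome", m), hM@dropped)
    if (nVariants(hM) >= 3) {
      eggerIntercepts[m] <- mrEgger(hM)$intercept@p
    }
    records[[m]] <- assessConcordance(ce, me, alpha = alphaGate,
                                      eggerInterceptP = eggerIntercepts[m],
                                      mediator = m)
  }
  risk <- do.call(rbind, riskRows)
  triRows <- if (length(records)) {
    do.call(rbind, lapply(records, .triangulationRow))
  } else {
    .triangulationRow(assessConcordance(
      totalCohort, totalMr, alpha = alphaGate, mediator = "none"))[0, ]
  }
  rownames(triRows) <- NULL

  ## stage 3: mediation, eligible mediators only
  mediationResults <- list()
  for (m in names(records)) {
    if (!records[[m]]@eligible) next
    mediationResults[[paste0("cohort.", m)]] <- stage(
      "mediation-cohort",
      mediateCohort(sim$cohort, m, "bmi", covars,
                    transform = config$cohort$transform))
    mediationResults[[paste0("mr.", m)]] <- stage(
      "mediation-mr",
      mediateMR(sim$sumstats$exposure, sim$sumstats$mediators[[m]],
                sim$sumstats$outcome, ld = ld,
                pThreshold = ic$p_threshold,
                r2Threshold = ic$r2_threshold, windowKb = ic$window_kb,
                palindromicWindow = ic$palindromic_window,
                model = mrCfg$model, steiger = isTRUE(mrCfg$steiger),
                presso = isTRUE(mrCfg$presso),
                pressoNSim = mrCfg$presso_n_sim,
                pressoSeed = config$seed + 1000L,
                weakFThreshold = mrCfg$weak_f_threshold,
                suppressWeak = isTRUE(mrCfg$suppress_weak)))
  }
  mediation <- if (length(mediationResults)) {
    do.call(rbind, lapply(mediationResults, .mediationRow))
  } else {
    .mediationRow(new("MediationResult", framework = "cohort",
                      mediator = "none", total = totalCohort,
                      directAdjusted = totalCohort, aPath =
                        .newEffectEstimate("none", 0, 1, "linear", TRUE),
                      bPath = .newEffectEstimate("none", 0, 1,
                                                 "log_hazard", TRUE),
                      indirectBeta = 0, indirectSe = 1,
                      indirectCi = c(-1.96, 1.96), directDifference = 0,
                      proportionMediated = 0, pmCi = c(0, 0),
                      pmOutOfRange = FALSE, weakInstrument = FALSE,
                      methodNotes = character(0)))[0, ]
  }
  rownames(mediation) <- NULL

  edges <- NULL
  if (length(meds) >= 2) {
    edges <- stage("pairwise", pairwiseRelations(
      sim$cohort, meds, sim$sumstats$mediators, ld = ld,
      covariates = covars, pThreshold = ic$p_threshold,
      r2Threshold = ic$r2_threshold, windowKb = ic$window_kb,
      palindromicWindow = ic$palindromic_window, model = mrCfg$model))
  }
  armR2 <- NA_real_
  if (length(meds) >= 2) {
    bc <- apath$beta[apath$framework == "cohort"]
    bm <- apath$beta[apath$framework == "mr"]
    if (length(bc) == length(bm) && length(bc) >= 2) {
      armR2 <- stats::cor(bc, bm)^2
    }
  }

  bundle <- list(
    config = config, simConfig = simCfg, groundTruth = sim$groundTruth,
    counts = list(
      n_cohort = nrow(sim$cohort), n_events = sum(sim$cohort$event),
      n_instruments_exposure = nVariants(instrX),
      mean_f_exposure = instrumentStrength(instrX)$meanF,
      n_eligible = sum(vapply(records, function(r) r@eligible,
                              logical(1)))),
    apath = apath, risk = risk,
    triangulation = triRows, triangulationRecords = records,
    mediation = mediation, mediationResults = mediationResults,
    edges = edges, armConcordanceR2 = armR2,
    droppedVariants = if (length(dropRows)) do.call(rbind, dropRows),
    eggerIntercepts = eggerIntercepts,
    cohortRisk = cohortRisk, mrRisk = mrRisk,
    totalCohort = totalCohort, totalMr = totalMr)
  if (!is.null(outDir)) writeTables(bundle, outDir,
                                    digits = config$output$digits)
  bundle
}
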