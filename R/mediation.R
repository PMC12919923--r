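#' @include cohort.R mr-mvmr.R
NULL

#' Product-method indirect effect with Sobel uncertainty
#'
#' The indirect effect of the exposure on the outcome through one mediator
#' is the product of the exposure-to-mediator coefficient (a, linear
#' scale) and the mediator-to-outcome coefficient adjusted for the
#' exposure (b, log-risk scale). The Sobel standard error treats the two
#' coefficients as independently estimated:
#' `se = sqrt(a^2 se_b^2 + b^2 se_a^2)`, with a normal 95% CI. A
#' Monte-Carlo interval (quantiles of products of draws from the two
#' sampling distributions) is available as a cross-check.
#'
#' @param a exposure-to-mediator [EffectEstimate-class] (scale `linear`).
#' @param b adjusted mediator-to-outcome [EffectEstimate-class] (scale
#'   `log_hazard` or `log_odds`).
#' @param nMc number of Monte-Carlo draws (0 disables).
#' @param mcSeed seed for the Monte-Carlo draws.
#' @return list with `indirect`, `se`, `ci` (Sobel), `scale`, and — when
#'   requested — `mcCi`.
#' @examples
#' a <- new("EffectEstimate", term = "bmi", estimate = 0.35, se = 0.02,
#'          p = 0, scale = "linear", perSd = TRUE,
#'          adjustment = character(0), n = NA_integer_,
#'          nEvents = NA_integer_, notes = character(0))
#' b <- new("EffectEstimate", term = "insulin", estimate = log(1.38),
#'          se = 0.17, p = 0.06, scale = "log_hazard", perSd = TRUE,
#'          adjustment = "bmi", n = NA_integer_, nEvents = NA_integer_,
#'          notes = character(0))
#' productIndirect(a, b)
#' @export
productIndirect <- function(a, b, nMc = 0, mcSeed = 1L) {
  .stopIfNot(a@scale == "linear",
             "a path must be on the linear (exposure-to-mediator) scale")
  .stopIfNot(b@scale %in% c("log_hazard", "log_odds"),
             "b path must be on a log-risk scale")
  indirect <- a@estimate * b@estimate
  se <- sqrt(a@estimate^2 * b@se^2 + b@estimate^2 * a@se^2)
  z <- stats::qnorm(0.975)
  out <- list(indirect = indirect, se = se,
              ci = indirect + c(-1, 1) * z * se, scale = b@scale)
  if (nMc > 0) {
    set.seed(mcSeed)
    draws <- stats::rnorm(nMc, a@estimate, a@se) *
      stats::rnorm(nMc, b@estimate, b@se)
    out$mcCi <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  out
}

#' Proportion mediated with delta-method uncertainty
#'
#' The proportion of the total exposure effect explained by the mediator,
#' `pm = indirect / total`, on the log-risk scale. The 95% CI is by the
#' first-order delta method treating the indirect and total estimates as
#' independent:
#' `var(pm) = se_I^2 / T^2 + I^2 se_T^2 / T^4`. Values outside [0, 1] are
#' reported verbatim with an out-of-range flag, never truncated.
#'
#' @param indirect,indirectSe indirect effect and its (Sobel) standard
#'   error.
#' @param total total-effect [EffectEstimate-class] (log-risk scale).
#' @return list with `pm`, `se`, `ci`, `outOfRange`.
#' @examples
#' tot <- new("EffectEstimate", term = "bmi", estimate = 0.4, se = 0.05,
#'            p = 0, scale = "log_hazard", perSd = TRUE,
#'            adjustment = character(0), n = NA_integer_,
#'            nEvents = NA_integer_, notes = character(0))
#' proportionMediated(0.1, 0.03, tot)
#' @export
proportionMediated <- function(indirect, indirectSe, total) {
  .stopIfNot(total@scale %in% c("log_hazard", "log_odds"),
             "total effect must be on a log-risk scale")
  .stopIfNot(total@estimate != 0, "total effect must be nonzero")
  t0 <- total@estimate
  pm <- indirect / t0
  se <- sqrt(indirectSe^2 / t0^2 + indirect^2 * total@se^2 / t0^4)
  z <- stats::qnorm(0.975)
  list(pm = pm, se = se, ci = pm + c(-1, 1) * z * se,
       outOfRange = pm < 0 || pm > 1)
}

.assembleMediation <- function(framework, mediator, a, b, total,
                               directAdjusted, weak = FALSE,
                               notes = character(0)) {
  prod <- productIndirect(a, b)
  pmRes <- proportionMediated(prod$indirect, prod$se, total)
  new("MediationResult", framework = framework, mediator = mediator,
      total = total, directAdjusted = directAdjusted, aPath = a, bPath = b,
      indirectBeta = prod$indirect, indirectSe = prod$se,
      indirectCi = prod$ci,
      directDifference = total@estimate - prod$indirect,
      proportionMediated = pmRes$pm, pmCi = pmRes$ci,
      pmOutOfRange = pmRes$outOfRange, weakInstrument = weak,
      methodNotes = notes)
}

#' Cohort-arm two-step mediation
#'
#' Assembles the product-method decomposition from cohort models: the a
#' path from the exposure-to-mediator linear model, the b path from the
#' mediator Cox model additionally adjusted for the exposure, and the
#' total effect from the exposure Cox model. The direct effect is
#' reported both as the exposure coefficient adjusted for the mediator
#' and as total minus indirect (difference method).
#'
#' The mediator is z-scored before modelling (unless `transform` says
#' otherwise), so the a path is in mediator SDs per exposure SD and the b
#' path in log-hazard per mediator SD; their product — and the proportion
#' mediated — is invariant to that scaling.
#'
#' @param cohort cohort `data.frame`.
#' @param mediator mediator column.
#' @param exposure exposure column.
#' @param covariates adjustment set.
#' @param transform mediator transformation (see [transformTrait()]).
#' @return a [MediationResult-class], framework `"cohort"`.
#' @export
mediateCohort <- function(cohort, mediator, exposure = "bmi",
                          covariates = c("age", "sex", "center",
                                         "education", "smoking",
                                         "alcohol"),
                          transform = "zscore") {
  df <- cohort
  df[[mediator]] <- as.numeric(transformTrait(df[[mediator]], transform))
  a <- apathLinear(df, mediator, exposure, covariates)
  b <- coxRisk(df, mediator, covariates, extraAdjust = exposure)
  total <- coxRisk(df, exposure, covariates)
  directAdj <- coxRisk(df, exposure, covariates, extraAdjust = mediator)
  .assembleMediation("cohort", mediator, a, b, total, directAdj,
                     notes = sprintf("a: linear; b: cox + %s; transform: %s",
                                     exposure, transform))
}

#' MR-arm two-step mediation
#'
#' Two-sample two-step decomposition from summary statistics: the a path
#' is the univariable IVW effect of the exposure on the mediator; the b
#' path is the mediator's multivariable-MR effect on the outcome with
#' adjustment for the exposure; the total effect is the univariable IVW
#' of the exposure on the outcome. When the mediator's conditional F is
#' below `weakFThreshold`, the weak-instrument flag is set and — when
#' `suppressWeak` — the indirect effect and proportion mediated are
#' reported as `NA` (the estimate is not calculated for lack of power).
#'
#' @param exposureSumstats,mediatorSumstats,outcomeSumstats
#'   [GwasSumstats-class] objects for the three traits.
#' @param ld pairwise LD table for clumping.
#' @param pThreshold,r2Threshold,windowKb instrument-selection settings.
#' @param palindromicWindow harmonization setting.
#' @param model IVW model (`"random"` or `"fixed"`).
#' @param steiger apply the Steiger filter to each harmonized set.
#' @param presso apply MR-PRESSO outlier removal (with `pressoNSim`
#'   simulations, seed `pressoSeed`) before estimation.
#' @param pressoNSim,pressoSeed,weakFThreshold,suppressWeak see above.
#' @return a [MediationResult-class], framework `"mr"`.
#' @export
mediateMR <- function(exposureSumstats, mediatorSumstats, outcomeSumstats,
                      ld = NULL, pThreshold = 5e-8, r2Threshold = 0.01,
                      windowKb = 10000, palindromicWindow = 0.08,
                      model = "random", steiger = FALSE, presso = FALSE,
                      pressoNSim = 1000, pressoSeed = 1L,
                      weakFThreshold = 10, suppressWeak = TRUE) {
  instrX <- selectInstruments(exposureSumstats, pThreshold, ld,
                              r2Threshold, windowKb)
  instrM <- selectInstruments(mediatorSumstats, pThreshold, ld,
                              r2Threshold, windowKb)
  .stopIfNot(nVariants(instrX) > 0, "no instruments for the exposure")
  .stopIfNot(nVariants(instrM) > 0, "no instruments for the mediator")
  refine <- function(h) {
    if (steiger) h <- steigerFilter(h)$filtered
    if (presso && nVariants(h) >= 4) {
      h <- mrPresso(h, nSim = pressoNSim, seed = pressoSeed)$filtered
    }
    h
  }
  hA <- refine(harmonize(instrX, mediatorSumstats, palindromicWindow))
  hT <- refine(harmonize(instrX, outcomeSumstats, palindromicWindow))
  a <- .asEffectEstimate(mrIvw(hA, model), "linear",
                         term = exposureSumstats@trait)
  total <- .asEffectEstimate(mrIvw(hT, model), "log_odds",
                             term = exposureSumstats@trait)
  joint <- unionInstruments(list(instrM, instrX), ld = ld)
  exposures <- stats::setNames(
    list(mediatorSumstats, exposureSumstats),
    c(mediatorSumstats@trait, exposureSumstats@trait))
  hB <- refine(harmonizeMulti(joint, exposures, outcomeSumstats,
                              palindromicWindow))
  mv <- mrMvmr(hB, weakFThreshold)
  bMre <- mv[[mediatorSumstats@trait]]
  directAdj <- .asEffectEstimate(mv[[exposureSumstats@trait]], "log_odds",
                                 term = exposureSumstats@trait)
  weak <- isTRUE(bMre@weakInstrument)
  b <- .asEffectEstimate(bMre, "log_odds", term = mediatorSumstats@trait)
  notes <- sprintf("a: ivw; b: mvmr adjusted for %s; conditional F = %.2f",
                   exposureSumstats@trait, bMre@conditionalF)
  res <- .assembleMediation("mr", mediatorSumstats@trait, a, b, total,
                            directAdj, weak = weak, notes = notes)
  if (weak && suppressWeak) {
    res@indirectBeta <- NA_real_
    res@indirectSe <- NA_real_
    res@indirectCi <- c(NA_real_, NA_real_)
    res@proportionMediated <- NA_real_
    res@pmCi <- c(NA_real_, NA_real_)
    res@methodNotes <- c(res@methodNotes,
                         "not calculated: conditional F below threshold")
  }
  res
}
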