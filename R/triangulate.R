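#' @include mediation.R
NULL

#' Concordance gate between the cohort and MR arms
#'
#' Mediation analysis is restricted to mediators whose risk associations
#' are directionally consistent in both the direct (cohort) and genetic
#' (MR) arms; this function evaluates that gate for one mediator:
#' direction agreement of the two log-risk estimates, significance of both
#' at `alpha`, and — when an MR-Egger intercept p-value is supplied — a
#' pleiotropy flag that marks (without vetoing) evidence of unbalanced
#' pleiotropy.
#'
#' @param cohortEstimate [EffectEstimate-class] on a log-risk scale
#'   (per SD).
#' @param mrEstimate [MREstimate-class] (per SD).
#' @param alpha significance gate (default 0.05; the gate, not a
#'   multiple-testing-corrected level).
#' @param eggerInterceptP optional MR-Egger intercept p-value.
#' @param pleiotropyAlpha threshold for the pleiotropy flag.
#' @param mediator mediator label.
#' @return a [TriangulationRecord-class].
#' @export
assessConcordance <- function(cohortEstimate, mrEstimate, alpha = 0.05,
                              eggerInterceptP = NA_real_,
                              pleiotropyAlpha = 0.05,
                              mediator = cohortEstimate@term) {
  .stopIfNot(cohortEstimate@scale %in% c("log_hazard", "log_odds"),
             "cohort estimate must be on a log-risk scale")
  concordant <- sign(cohortEstimate@estimate) == sign(mrEstimate@estimate)
  bothSig <- cohortEstimate@p < alpha && mrEstimate@p < alpha
  new("TriangulationRecord", mediator = mediator,
      cohortEstimate = cohortEstimate, mrEstimate = mrEstimate,
      directionallyConcordant = concordant, bothSignificant = bothSig,
      alpha = alpha, eligible = concordant && bothSig,
      pleiotropyFlag = if (is.na(eggerInterceptP)) NA
                       else eggerInterceptP < pleiotropyAlpha)
}

#' Pairwise mediator-mediator relations in both arms
#'
#' Re-applies the a-path machinery to every ordered pair of mediators:
#' in the cohort arm a linear model of mediator j on mediator i (per SD,
#' with the adjustment set); in the MR arm the univariable IVW estimate
#' using mediator i's instruments against mediator j's summary
#' statistics. Both directions of every pair are estimated, so
#' bidirectional relations are visible; a mediator is never regressed on
#' itself. The edge table has `2 * choose(K, 2)` rows per framework.
#'
#' @param cohort cohort `data.frame`.
#' @param mediatorNames mediator columns (length >= 2).
#' @param sumstatsList named list of [GwasSumstats-class], one per
#'   mediator.
#' @param ld LD table for clumping.
#' @param covariates cohort adjustment set.
#' @param pThreshold,r2Threshold,windowKb,palindromicWindow,model MR
#'   settings.
#' @return `data.frame` with columns `from`, `to`, `framework`, `beta`,
#'   `se`, `p`, `nVariants`.
#' @export
pairwiseRelations <- function(cohort, mediatorNames, sumstatsList,
                              ld = NULL,
                              covariates = c("age", "sex", "center",
                                             "education", "smoking",
                                             "alcohol"),
                              pThreshold = 5e-8, r2Threshold = 0.01,
                              windowKb = 10000, palindromicWindow = 0.08,
                              model = "random") {
  .stopIfNot(length(mediatorNames) >= 2,
             "pairwise relations need at least two mediators")
  rows <- list()
  df <- cohort
  for (m in mediatorNames) {
    df[[m]] <- as.numeric(transformTrait(df[[m]], "zscore"))
  }
  for (i in mediatorNames) {
    instr <- tryCatch(
      selectInstruments(sumstatsList[[i]], pThreshold, ld, r2Threshold,
                        windowKb),
      warning = function(w) NULL)
    for (j in setdiff(mediatorNames, i)) {
      a <- apathLinear(df, j, exposure = i, covariates = covariates)
      rows[[length(rows) + 1L]] <- data.frame(
        from = i, to = j, framework = "cohort", beta = a@estimate,
        se = a@se, p = a@p, nVariants = NA_integer_,
        stringsAsFactors = FALSE)
      if (!is.null(instr) && nVariants(instr) > 0) {
        h <- harmonize(instr, sumstatsList[[j]], palindromicWindow)
        if (nVariants(h) > 0) {
          mre <- suppressWarnings(mrIvw(h, model))
          rows[[length(rows) + 1L]] <- data.frame(
            from = i, to = j, framework = "mr", beta = mre@estimate,
            se = mre@se, p = mre@p, nVariants = mre@nVariants,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
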