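#' @include simulate-gwas.R simulate-ncc.R
NULL

#' Simulate a complete two-arm study
#'
#' Generates, under one seed, everything the pipeline consumes: the
#' longitudinal cohort, and summary statistics from two GWAS arms drawn
#' from non-overlapping individuals (the two-sample assumption) — the
#' exposure arm supplies exposure and mediator GWAS (continuous traits),
#' the outcome arm a case-control GWAS of the event indicator. All samples
#' share one variant panel, so the per-allele generative effects are
#' identical across arms. An LD table computed from the exposure-arm
#' genotypes is included for clumping.
#'
#' @param config a [SimulationConfig-class].
#' @param components subset of `c("cohort", "gwas")` to generate.
#' @return list with elements `config`, `panel`, `groundTruth`, `cohort`
#'   (plus `linearPredictor`, `confounder`), `sumstats` (list: `exposure`,
#'   `mediators` (named list), `outcome`) and `ld`.
#' @examples
#' cfg <- simulationConfig(nIndividuals = 1500, gwasNExposureArm = 1500,
#'                         gwasNOutcomeArm = 1500, nSnpsExposure = 10,
#'                         nSnpsMediator = 5, baselineHazard = 0.01)
#' sim <- simulateStudy(cfg)
#' sim$groundTruth
#' @export
simulateStudy <- function(config, components = c("cohort", "gwas")) {
  validObject(config)
  set.seed(config@seed)
  panel <- simulateVariantPanel(config)
  out <- list(config = config, panel = panel,
              groundTruth = groundTruth(config))
  if ("cohort" %in% components) {
    g <- simulateGenotypes(config, n = config@nIndividuals, panel = panel)
    sim <- simulateTraits(g$genotypes, panel, config, idPrefix = "C")
    out$cohort <- sim$cohort
    out$linearPredictor <- sim$linearPredictor
    out$confounder <- sim$confounder
    out$cohortGenotypes <- g$genotypes
  }
  if ("gwas" %in% components) {
    gA <- simulateGenotypes(config, n = config@gwasNExposureArm,
                            panel = panel)
    simA <- simulateTraits(gA$genotypes, panel, config, idPrefix = "A")
    out$sumstats <- list(
      exposure = computeSummaryStats(gA$genotypes, simA$cohort$bmi, panel,
                                     type = "continuous",
                                     traitName = "bmi"),
      mediators = stats::setNames(lapply(config@mediatorNames, function(m) {
        computeSummaryStats(gA$genotypes, simA$cohort[[m]], panel,
                            type = "continuous", traitName = m)
      }), config@mediatorNames)
    )
    out$ld <- ldFromGenotypes(gA$genotypes, panel)
    gB <- simulateGenotypes(config, n = config@gwasNOutcomeArm,
                            panel = panel)
    simB <- simulateTraits(gB$genotypes, panel, config, idPrefix = "B")
    out$sumstats$outcome <- computeSummaryStats(
      gB$genotypes, simB$cohort$event, panel, type = "binary",
      traitName = "outcome")
  }
  out
}
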