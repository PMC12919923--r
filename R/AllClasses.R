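#' @import methods
NULL

## Canonical GWAS-SSF-like column set used by every summary-statistics table.
.SUMSTATS_COLS <- c(
  "variant_id", "chromosome", "base_pair_location", "effect_allele",
  "other_allele", "effect_allele_frequency", "beta", "standard_error",
  "p_value", "n"
)

.validSumstatsData <- function(df) {
  missing <- setdiff(.SUMSTATS_COLS, names(df))
  if (length(missing)) {
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  msgs <- character(0)
  num <- c("base_pair_location", "effect_allele_frequency", "beta",
           "standard_error", "p_value", "n")
  for (col in num) {
    if (!is.numeric(df[[col]])) msgs <- c(msgs, sprintf("column '%s' must be numeric", col))
  }
  if (length(msgs)) return(msgs)
  if (nrow(df) == 0L) return(TRUE)
  if (any(df$standard_error <= 0)) msgs <- c(msgs, "standard_error must be > 0")
  if (any(df$p_value <= 0 | df$p_value > 1)) msgs <- c(msgs, "p_value must lie in (0, 1]")
  if (any(df$effect_allele_frequency <= 0 | df$effect_allele_frequency >= 1)) {
    msgs <- c(msgs, "effect_allele_frequency must lie in (0, 1)")
  }
  ok <- c("A", "C", "G", "T")
  if (!all(df$effect_allele %in% ok) || !all(df$other_allele %in% ok)) {
    msgs <- c(msgs, "alleles must be single bases A/C/G/T")
  }
  if (any(df$effect_allele == df$other_allele)) {
    msgs <- c(msgs, "effect and other allele must differ")
  }
  if (length(msgs)) msgs else TRUE
}

#' GWAS summary statistics for one trait
#'
#' A validated container for per-variant association records (one row per
#' variant: identifier, position, alleles, effect-allele frequency, beta,
#' standard error, p-value, sample size), the unit record of both the
#' exposure and outcome arms of a two-sample Mendelian randomization
#' analysis.
#'
#' @slot data a `data.frame` with the canonical columns `variant_id`,
#'   `chromosome`, `base_pair_location`, `effect_allele`, `other_allele`,
#'   `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`.
#' @slot trait name of the trait the statistics refer to.
#' @exportClass GwasSumstats
setClass("GwasSumstats",
  slots = c(data = "data.frame", trait = "character"),
  validity = function(object) {
    if (length(object@trait) != 1L) return("trait must be a single string")
    .validSumstatsData(object@data)
  }
)

#' A set of genetic instruments for one exposure
#'
#' Variants retained after the genome-wide significance filter and greedy
#' LD clumping, together with the thresholds that produced them.
#'
#' @slot data summary-statistics rows of the retained variants.
#' @slot exposure exposure trait name.
#' @slot pThreshold p-value threshold applied (variants with p above it are
#'   excluded).
#' @slot r2Threshold pairwise LD r-squared above which a neighbour of a
#'   retained index variant is pruned.
#' @slot windowKb clumping window in kilobases.
#' @exportClass InstrumentSet
setClass("InstrumentSet",
  slots = c(data = "data.frame", exposure = "character",
            pThreshold = "numeric", r2Threshold = "numeric",
            windowKb = "numeric"),
  validity = function(object) {
    msgs <- character(0)
    v <- .validSumstatsData(object@data)
    if (!isTRUE(v)) msgs <- c(msgs, v)
    if (nrow(object@data) && any(object@data$p_value > object@pThreshold)) {
      msgs <- c(msgs, "all instruments must satisfy p <= pThreshold")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Harmonized exposure/outcome effects on a common effect allele
#'
#' Per-variant exposure (possibly several exposures, for multivariable MR)
#' and outcome effects aligned so every beta is expressed relative to the
#' exposure's effect allele; the substrate of every MR estimator. Variants
#' removed on the way are kept with a reason code (`missing_in_outcome`,
#' `missing_in_exposure`, `palindromic_ambiguous`, `allele_mismatch`,
#' `presso_outlier`, `steiger_reverse`).
#'
#' @slot variants `data.frame` of variant annotation (id, position, aligned
#'   alleles, exposure/outcome effect-allele frequencies).
#' @slot betaExposure,seExposure,nExposure J x K matrices of exposure
#'   effects, standard errors and sample sizes (K exposures).
#' @slot betaOutcome,seOutcome,nOutcome outcome effect vectors (length J).
#' @slot exposures,outcome trait names.
#' @slot dropped `data.frame` with columns `variant_id`, `reason`.
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  slots = c(variants = "data.frame",
            betaExposure = "matrix", seExposure = "matrix",
            nExposure = "matrix",
            betaOutcome = "numeric", seOutcome = "numeric",
            nOutcome = "numeric",
            exposures = "character", outcome = "character",
            dropped = "data.frame"),
  validity = function(object) {
    msgs <- character(0)
    J <- nrow(object@betaExposure)
    K <- ncol(object@betaExposure)
    if (nrow(object@variants) != J) msgs <- c(msgs, "variants/beta dimension mismatch")
    for (s in c("seExposure", "nExposure")) {
      m <- slot(object, s)
      if (!all(dim(m) == c(J, K))) msgs <- c(msgs, sprintf("%s dimension mismatch", s))
    }
    for (s in c("betaOutcome", "seOutcome", "nOutcome")) {
      if (length(slot(object, s)) != J) msgs <- c(msgs, sprintf("%s length mismatch", s))
    }
    if (length(object@exposures) != K) msgs <- c(msgs, "exposures length mismatch")
    if (J && any(object@seExposure <= 0)) msgs <- c(msgs, "exposure se must be > 0")
    if (J && any(object@seOutcome <= 0)) msgs <- c(msgs, "outcome se must be > 0")
    if (!all(c("variant_id", "reason") %in% names(object@dropped))) {
      msgs <- c(msgs, "dropped must have variant_id and reason columns")
    }
    if (J && anyDuplicated(object@variants$variant_id)) {
      msgs <- c(msgs, "duplicate variant identifiers")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' A single Mendelian randomization estimate
#'
#' One coefficient on the outcome scale per standard-deviation (or stated
#' unit) increment of the exposure, with its uncertainty and heterogeneity
#' companions. When the outcome is binary the exponentiated estimate is an
#' odds ratio.
#'
#' @slot method one of `wald`, `ivw_fixed`, `ivw_random`, `egger_slope`,
#'   `egger_intercept`, `mvmr`.
#' @slot exposure,outcome trait names.
#' @slot estimate,se,p point estimate (log scale for binary outcomes),
#'   standard error and two-sided normal p-value.
#' @slot ciLow,ciHigh 95% confidence bounds (estimate -/+ 1.96 se).
#' @slot nVariants number of instruments used.
#' @slot qStatistic,qP Cochran's Q heterogeneity statistic and p-value
#'   (`NA` where not defined).
#' @slot conditionalF conditional F statistic (multivariable MR only).
#' @slot weakInstrument flag set when conditional F < 10.
#' @exportClass MREstimate
setClass("MREstimate",
  slots = c(method = "character", exposure = "character",
            outcome = "character", estimate = "numeric", se = "numeric",
            p = "numeric", ciLow = "numeric", ciHigh = "numeric",
            nVariants = "integer", qStatistic = "numeric", qP = "numeric",
            conditionalF = "numeric", weakInstrument = "logical"),
  validity = function(object) {
    msgs <- character(0)
    ok <- c("wald", "ivw_fixed", "ivw_random", "egger_slope",
            "egger_intercept", "mvmr")
    if (!object@method %in% ok) msgs <- c(msgs, "unknown method")
    if (!is.na(object@se) && object@se < 0) msgs <- c(msgs, "se must be >= 0")
    z <- stats::qnorm(0.975)
    if (!is.na(object@se) && is.finite(object@estimate)) {
      tol <- 1e-8 + 1e-6 * object@se
      if (abs(object@ciLow - (object@estimate - z * object@se)) > tol ||
          abs(object@ciHigh - (object@estimate + z * object@se)) > tol) {
        msgs <- c(msgs, "confidence bounds must equal estimate -/+ 1.96 se")
      }
    }
    if (!is.na(object@qStatistic) && object@qStatistic < -1e-8) {
      msgs <- c(msgs, "q statistic must be >= 0")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' A single cohort-arm coefficient
#'
#' The common currency of the direct-assessment arm: one coefficient with
#' an explicit scale descriptor (`linear` for exposure-to-mediator models,
#' `log_hazard` for Cox models, `log_odds` for (conditional) logistic
#' models), its adjustment set, and provenance of any per-SD scaling.
#'
#' @slot term modelled term.
#' @slot estimate,se,p coefficient, standard error, p-value.
#' @slot scale one of `linear`, `log_hazard`, `log_odds`.
#' @slot perSd whether the term was scaled per sample standard deviation.
#' @slot adjustment covariates adjusted for.
#' @slot n,nEvents analysis sample size and number of events (`NA` for
#'   linear models).
#' @slot notes free-text provenance (transformations, flags).
#' @exportClass EffectEstimate
setClass("EffectEstimate",
  slots = c(term = "character", estimate = "numeric", se = "numeric",
            p = "numeric", scale = "character", perSd = "logical",
            adjustment = "character", n = "integer", nEvents = "integer",
            notes = "character"),
  validity = function(object) {
    msgs <- character(0)
    if (!object@scale %in% c("linear", "log_hazard", "log_odds")) {
      msgs <- c(msgs, "scale must be linear, log_hazard or log_odds")
    }
    if (!is.na(object@se) && object@se < 0) msgs <- c(msgs, "se must be >= 0")
    if (length(msgs)) msgs else TRUE
  }
)

#' Result of a two-step product-method mediation analysis
#'
#' Total, direct and indirect effects of the exposure on the outcome through
#' one mediator, with the proportion mediated, tagged by the framework that
#' produced the paths (cohort or MR).
#'
#' @slot framework `"cohort"` or `"mr"`.
#' @slot mediator mediator name.
#' @slot total total-effect estimate (log-risk scale).
#' @slot directAdjusted exposure effect adjusted for the mediator.
#' @slot aPath,bPath the two product-method ingredients.
#' @slot indirectBeta,indirectSe product-method indirect effect (a x b) and
#'   its Sobel standard error.
#' @slot indirectCi 95% CI for the indirect effect.
#' @slot directDifference total minus indirect (difference-method direct
#'   effect).
#' @slot proportionMediated indirect/total on the log-risk scale.
#' @slot pmCi delta-method 95% CI for the proportion mediated.
#' @slot pmOutOfRange flag: proportion outside [0, 1] (reported verbatim,
#'   never truncated).
#' @slot weakInstrument weak-instrument flag propagated from the MR b-path.
#' @slot methodNotes provenance of the a and b paths.
#' @exportClass MediationResult
setClass("MediationResult",
  slots = c(framework = "character", mediator = "character",
            total = "EffectEstimate", directAdjusted = "EffectEstimate",
            aPath = "EffectEstimate", bPath = "EffectEstimate",
            indirectBeta = "numeric", indirectSe = "numeric",
            indirectCi = "numeric", directDifference = "numeric",
            proportionMediated = "numeric", pmCi = "numeric",
            pmOutOfRange = "logical", weakInstrument = "logical",
            methodNotes = "character"),
  validity = function(object) {
    msgs <- character(0)
    if (!object@framework %in% c("cohort", "mr")) {
      msgs <- c(msgs, "framework must be 'cohort' or 'mr'")
    }
    prod <- object@aPath@estimate * object@bPath@estimate
    if (is.finite(prod) && is.finite(object@indirectBeta) &&
        abs(prod - object@indirectBeta) > 1e-8 * (1 + abs(prod))) {
      msgs <- c(msgs, "indirect effect must equal the a x b product")
    }
    if (length(object@indirectCi) != 2L || length(object@pmCi) != 2L) {
      msgs <- c(msgs, "confidence intervals must have length 2")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Cross-arm concordance record for one mediator
#'
#' Stores the cohort and MR risk estimates for one mediator together with
#' the eligibility gate used to decide whether mediation analysis proceeds:
#' a mediator is eligible when both arms are significant at `alpha` and the
#' two estimates agree in direction.
#'
#' @slot mediator mediator name.
#' @slot cohortEstimate cohort-arm risk estimate (log-hazard or log-odds
#'   per SD).
#' @slot mrEstimate MR-arm risk estimate (log-odds per SD).
#' @slot directionallyConcordant sign agreement of the two estimates.
#' @slot bothSignificant both p-values below alpha.
#' @slot alpha significance gate used.
#' @slot eligible `directionallyConcordant && bothSignificant`.
#' @slot pleiotropyFlag MR-Egger intercept p below its threshold (`NA` when
#'   no Egger fit was available).
#' @exportClass TriangulationRecord
setClass("TriangulationRecord",
  slots = c(mediator = "character", cohortEstimate = "EffectEstimate",
            mrEstimate = "MREstimate", directionallyConcordant = "logical",
            bothSignificant = "logical", alpha = "numeric",
            eligible = "logical", pleiotropyFlag = "logical"),
  validity = function(object) {
    if (!identical(object@eligible,
                   object@directionallyConcordant && object@bothSignificant)) {
      return("eligible must equal directionallyConcordant AND bothSignificant")
    }
    TRUE
  }
)

#' Configuration of the synthetic study generator
#'
#' Parameters of the generative model: a polygenic BMI-like exposure,
#' mediators causally downstream of the exposure with their own genetic
#' effects, an unmeasured standard-normal confounder loading on exposure,
#' mediators and outcome, and a rare exponential time-to-event outcome
#' censored administratively. Two GWAS arms are drawn from non-overlapping
#' individuals, as the two-sample design assumes.
#'
#' Effects are on the scales used throughout the package: `betaXM` in
#' mediator units per SD of exposure, `betaMY` and `betaXYdirect` in
#' log-hazard units, `confounderStrength` per SD of the latent confounder.
#'
#' @slot seed RNG seed.
#' @slot nIndividuals cohort size.
#' @slot nSnpsExposure,nSnpsMediator instruments per trait (`nSnpsMediator`
#'   per mediator; 0 allowed).
#' @slot nMediators number of mediators.
#' @slot mediatorNames mediator column names.
#' @slot mafRange minor-allele-frequency range, within (0.01, 0.5].
#' @slot ldBlockSize,ldRho,ldStructure LD-block size, adjacent-variant
#'   genotype correlation in [0, 1), and latent structure (`"ar1"` or
#'   `"exchangeable"`).
#' @slot h2Exposure,h2Mediator variance fractions explained by the genetic
#'   scores.
#' @slot betaXM exposure-to-mediator effects (length `nMediators`).
#' @slot betaMY mediator log-hazard effects (length `nMediators`).
#' @slot betaMM chain effect of mediator k-1 on mediator k.
#' @slot betaXYdirect direct exposure log-hazard effect.
#' @slot confounderStrength loading of the latent confounder.
#' @slot ageEffectExposure,ageEffectHazard,sexEffectHazard measured-covariate
#'   loadings (age standardized; sex indicator 1 = male).
#' @slot baselineHazard events per person-year at the linear-predictor
#'   origin.
#' @slot followupYears administrative censoring time.
#' @slot gwasNExposureArm,gwasNOutcomeArm sizes of the two GWAS arms.
#' @slot effectDistribution `"normal"` (per-variant effects drawn
#'   N(0, 1) before scaling — a realistic spread of instrument strengths)
#'   or `"equal"` (equal magnitudes with random signs, so every variant
#'   is a genuine genome-wide-significant instrument at the default
#'   sizes).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(seed = "numeric", nIndividuals = "numeric",
            nSnpsExposure = "numeric", nSnpsMediator = "numeric",
            nMediators = "numeric", mediatorNames = "character",
            mafRange = "numeric", ldBlockSize = "numeric", ldRho = "numeric",
            ldStructure = "character", h2Exposure = "numeric",
            h2Mediator = "numeric", betaXM = "numeric", betaMY = "numeric",
            betaMM = "numeric", betaXYdirect = "numeric",
            confounderStrength = "numeric", ageEffectExposure = "numeric",
            ageEffectHazard = "numeric", sexEffectHazard = "numeric",
            baselineHazard = "numeric", followupYears = "numeric",
            gwasNExposureArm = "numeric", gwasNOutcomeArm = "numeric",
            effectDistribution = "character"),
  validity = function(object) {
    msgs <- character(0)
    pos <- c("nIndividuals", "nSnpsExposure", "ldBlockSize",
             "baselineHazard", "followupYears", "gwasNExposureArm",
             "gwasNOutcomeArm")
    for (s in pos) {
      v <- slot(object, s)
      if (length(v) != 1L || is.na(v) || v <= 0) {
        msgs <- c(msgs, sprintf("%s must be a positive scalar", s))
      }
    }
    if (object@nSnpsMediator < 0) msgs <- c(msgs, "nSnpsMediator must be >= 0")
    K <- object@nMediators
    if (K < 0) msgs <- c(msgs, "nMediators must be >= 0")
    if (length(object@betaXM) != K || length(object@betaMY) != K) {
      msgs <- c(msgs, "betaXM and betaMY must have length nMediators")
    }
    if (length(object@mediatorNames) != K) {
      msgs <- c(msgs, "mediatorNames must have length nMediators")
    }
    if (length(object@mafRange) != 2L ||
        object@mafRange[1] <= 0.01 || object@mafRange[2] > 0.5 ||
        object@mafRange[1] > object@mafRange[2]) {
      msgs <- c(msgs, "mafRange must lie within (0.01, 0.5]")
    }
    if (object@ldRho < 0 || object@ldRho >= 1) {
      msgs <- c(msgs, "ldRho must lie in [0, 1)")
    }
    if (!object@ldStructure %in% c("ar1", "exchangeable")) {
      msgs <- c(msgs, "ldStructure must be 'ar1' or 'exchangeable'")
    }
    if (!object@effectDistribution %in% c("normal", "equal")) {
      msgs <- c(msgs, "effectDistribution must be 'normal' or 'equal'")
    }
    budgetX <- object@h2Exposure + object@confounderStrength^2 +
      object@ageEffectExposure^2
    if (object@h2Exposure <= 0 || budgetX >= 1) {
      msgs <- c(msgs, "exposure variance budget (h2 + confounder^2 + age^2) must stay below 1")
    }
    budgetM <- object@h2Mediator + object@confounderStrength^2
    if (K > 0 && (object@h2Mediator < 0 || budgetM >= 1)) {
      msgs <- c(msgs, "mediator variance budget (h2 + confounder^2) must stay below 1")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Closed-form estimands of the simulated world
#'
#' The mediation estimands implied by a [SimulationConfig] on the log-hazard
#' scale: total effect of one SD of exposure, the direct effect, per-mediator
#' indirect effects (product of the exposure-to-mediator path and the
#' mediator log-hazard), and proportions mediated. On the log scale
#' total = direct + sum(indirect) exactly.
#'
#' @slot totalLogEffect,directLogEffect scalars (log-hazard per SD).
#' @slot indirectLogEffect,proportionMediated per-mediator vectors.
#' @slot mediatorNames mediator names.
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(totalLogEffect = "numeric", directLogEffect = "numeric",
            indirectLogEffect = "numeric", proportionMediated = "numeric",
            mediatorNames = "character"),
  validity = function(object) {
    tot <- object@directLogEffect + sum(object@indirectLogEffect)
    if (abs(tot - object@totalLogEffect) > 1e-8 * (1 + abs(tot))) {
      return("total must equal direct + sum(indirect) on the log scale")
    }
    TRUE
  }
)
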