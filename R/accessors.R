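#' @include AllGenerics.R
NULL

#' @rdname estimate
setMethod("estimate", "MREstimate", function(object) object@estimate)
#' @rdname estimate
setMethod("estimate", "EffectEstimate", function(object) object@estimate)
#' @rdname estimate
setMethod("stdError", "MREstimate", function(object) object@se)
#' @rdname estimate
setMethod("stdError", "EffectEstimate", function(object) object@se)
#' @rdname estimate
setMethod("pValue", "MREstimate", function(object) object@p)
#' @rdname estimate
setMethod("pValue", "EffectEstimate", function(object) object@p)
#' @rdname estimate
setMethod("confInt", "MREstimate", function(object) {
  c(object@ciLow, object@ciHigh)
})
#' @rdname estimate
setMethod("confInt", "EffectEstimate", function(object) {
  z <- stats::qnorm(0.975)
  object@estimate + c(-1, 1) * z * object@se
})
#' @rdname estimate
setMethod("oddsRatio", "MREstimate", function(object) {
  c(or = exp(object@estimate), ciLow = exp(object@ciLow),
    ciHigh = exp(object@ciHigh))
})
#' @rdname estimate
setMethod("oddsRatio", "EffectEstimate", function(object) {
  if (object@scale == "linear") {
    stop("oddsRatio() is only meaningful for log-scale estimates")
  }
  ci <- confInt(object)
  c(or = exp(object@estimate), ciLow = exp(ci[1]), ciHigh = exp(ci[2]))
})

#' @rdname variants
setMethod("variants", "HarmonizedSet", function(object) object@variants)
#' @rdname variants
setMethod("variants", "InstrumentSet", function(object) object@data)
#' @rdname variants
setMethod("variants", "GwasSumstats", function(object) object@data)
#' @rdname variants
setMethod("droppedVariants", "HarmonizedSet", function(object) object@dropped)
#' @rdname variants
setMethod("exposureNames", "HarmonizedSet", function(object) object@exposures)
#' @rdname variants
setMethod("nVariants", "HarmonizedSet", function(object) nrow(object@variants))
#' @rdname variants
setMethod("nVariants", "InstrumentSet", function(object) nrow(object@data))
#' @rdname variants
setMethod("nVariants", "GwasSumstats", function(object) nrow(object@data))

setMethod("show", "GwasSumstats", function(object) {
  cat(sprintf("GwasSumstats for trait '%s': %d variants\n",
              object@trait, nrow(object@data)))
  if (nrow(object@data)) {
    print(utils::head(object@data, 3L), row.names = FALSE)
    if (nrow(object@data) > 3L) cat("  ...\n")
  }
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf(
    "InstrumentSet for '%s': %d instruments (p <= %.3g, r2 <= %.3g within %g kb)\n",
    object@exposure, nrow(object@data), object@pThreshold,
    object@r2Threshold, object@windowKb))
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %d variants, exposure(s) [%s] -> outcome '%s'\n",
              nrow(object@variants),
              paste(object@exposures, collapse = ", "), object@outcome))
  if (nrow(object@dropped)) {
    tab <- table(object@dropped$reason)
    cat("  dropped:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  }
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf(
    "MREstimate [%s] %s -> %s\n  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, J = %d\n",
    object@method, object@exposure, object@outcome, object@estimate,
    object@se, object@ciLow, object@ciHigh, object@p, object@nVariants))
  if (!is.na(object@qStatistic)) {
    cat(sprintf("  Cochran's Q = %.3f (p = %.3g)\n",
                object@qStatistic, object@qP))
  }
  if (!is.na(object@conditionalF)) {
    cat(sprintf("  conditional F = %.2f%s\n", object@conditionalF,
                if (isTRUE(object@weakInstrument)) " [weak instrument]" else ""))
  }
})

setMethod("show", "EffectEstimate", function(object) {
  ci <- confInt(object)
  cat(sprintf(
    "EffectEstimate '%s' (%s%s): beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
    object@term, object@scale, if (isTRUE(object@perSd)) ", per SD" else "",
    object@estimate, object@se, ci[1], ci[2], object@p))
  if (length(object@adjustment)) {
    cat("  adjusted for:", paste(object@adjustment, collapse = ", "), "\n")
  }
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("MediationResult [%s arm] mediator '%s'\n",
              object@framework, object@mediator))
  cat(sprintf("  total      = %.4f (se %.4f)\n",
              object@total@estimate, object@total@se))
  cat(sprintf("  indirect   = %.4f (Sobel se %.4f), 95%% CI [%.4f, %.4f]\n",
              object@indirectBeta, object@indirectSe,
              object@indirectCi[1], object@indirectCi[2]))
  cat(sprintf("  proportion mediated = %.3f, 95%% CI [%.3f, %.3f]%s\n",
              object@proportionMediated, object@pmCi[1], object@pmCi[2],
              if (isTRUE(object@pmOutOfRange)) " [out of range]" else ""))
  if (isTRUE(object@weakInstrument)) cat("  weak-instrument flag set\n")
})

setMethod("show", "TriangulationRecord", function(object) {
  cat(sprintf(
    "TriangulationRecord '%s': cohort beta %.4f (p %.3g), MR beta %.4f (p %.3g)\n",
    object@mediator, object@cohortEstimate@estimate, object@cohortEstimate@p,
    object@mrEstimate@estimate, object@mrEstimate@p))
  cat(sprintf("  concordant = %s, both significant (alpha %.3g) = %s -> eligible = %s\n",
              object@directionallyConcordant, object@alpha,
              object@bothSignificant, object@eligible))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: n = %d, %d exposure + %d x %d mediator SNPs, seed %d\n",
    as.integer(object@nIndividuals), as.integer(object@nSnpsExposure),
    as.integer(object@nMediators), as.integer(object@nSnpsMediator),
    as.integer(object@seed)))
  cat(sprintf("  betaXM = [%s], betaMY = [%s], direct = %.3f, confounder = %.2f\n",
              paste(format(object@betaXM, digits = 3), collapse = ", "),
              paste(format(object@betaMY, digits = 3), collapse = ", "),
              object@betaXYdirect, object@confounderStrength))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: total = %.4f, direct = %.4f\n",
              object@totalLogEffect, object@directLogEffect))
  for (k in seq_along(object@mediatorNames)) {
    cat(sprintf("  %s: indirect = %.4f, proportion mediated = %.3f\n",
                object@mediatorNames[k], object@indirectLogEffect[k],
                object@proportionMediated[k]))
  }
})
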