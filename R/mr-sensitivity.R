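#' @include mr-estimators.R
NULL

## Leave-one-out IVW slopes for every variant, O(J) via totals.
.looSlopes <- function(x, y, w) {
  Swxy <- sum(w * x * y)
  Swxx <- sum(w * x^2)
  (Swxy - w * x * y) / (Swxx - w * x^2)
}

#' MR-PRESSO global pleiotropy test and outlier detection
#'
#' Compares the observed weighted residual sum of squares of the
#' leave-one-out IVW fit with its parametric null distribution: in each of
#' `nSim` simulations, exposure and outcome betas are redrawn from normal
#' distributions centred on the observed exposure betas and on the
#' leave-one-out fitted outcome betas, and the statistic is recomputed.
#' The global p-value is the (add-one) simulation tail probability.
#' Per-variant observed squared residuals are compared with their
#' simulated distributions to give outlier p-values, thresholded at
#' `alphaOutlier` with Bonferroni correction over variants; flagged
#' variants are removed from the returned set with reason
#' `presso_outlier`.
#'
#' @param h a [HarmonizedSet-class] with at least 4 variants.
#' @param nSim number of parametric simulations (at least 100).
#' @param seed RNG seed (mandatory: the outlier list must be
#'   reproducible).
#' @param alphaOutlier familywise outlier level.
#' @return list with `globalP`, `outliers` (variant ids), `outlierP`
#'   (named vector) and `filtered` (the pruned [HarmonizedSet-class]).
#' @export
mrPresso <- function(h, nSim = 1000, seed, alphaOutlier = 0.05) {
  .stopIfNot(nVariants(h) >= 4, "MR-PRESSO requires at least 4 variants")
  .stopIfNot(nSim >= 100, "nSim must be at least 100")
  .stopIfNot(!missing(seed), "a seed is required")
  set.seed(seed)
  x <- h@betaExposure[, 1]
  sx <- h@seExposure[, 1]
  y <- h@betaOutcome
  sy <- h@seOutcome
  J <- length(x)
  w <- 1 / sy^2
  slopes <- .looSlopes(x, y, w)
  obsRes2 <- w * (y - slopes * x)^2
  rssObs <- sum(obsRes2)
  ## parametric simulations, vectorized across replicates
  xs <- matrix(stats::rnorm(nSim * J, mean = rep(x, each = nSim),
                            sd = rep(sx, each = nSim)), nSim, J)
  ys <- matrix(stats::rnorm(nSim * J, mean = rep(slopes * x, each = nSim),
                            sd = rep(sy, each = nSim)), nSim, J)
  W <- matrix(w, nSim, J, byrow = TRUE)
  Swxy <- rowSums(W * xs * ys)
  Swxx <- rowSums(W * xs^2)
  looS <- (Swxy - W * xs * ys) / (Swxx - W * xs^2)
  simRes2 <- W * (ys - looS * xs)^2
  rssSim <- rowSums(simRes2)
  globalP <- (1 + sum(rssSim >= rssObs)) / (nSim + 1)
  outlierP <- (1 + colSums(simRes2 >= rep(obsRes2, each = nSim))) /
    (nSim + 1)
  names(outlierP) <- h@variants$variant_id
  outliers <- names(outlierP)[outlierP < alphaOutlier / J]
  filtered <- .dropVariants(h, outliers, "presso_outlier")
  list(globalP = globalP, outliers = outliers, outlierP = outlierP,
       filtered = filtered)
}

## Remove variants from a harmonized set, recording the reason.
.dropVariants <- function(h, ids, reason) {
  keep <- !h@variants$variant_id %in% ids
  dropped <- h@dropped
  if (any(!keep)) {
    dropped <- rbind(dropped, data.frame(
      variant_id = h@variants$variant_id[!keep], reason = reason,
      stringsAsFactors = FALSE))
  }
  variants <- h@variants[keep, , drop = FALSE]
  rownames(variants) <- NULL
  new("HarmonizedSet", variants = variants,
      betaExposure = h@betaExposure[keep, , drop = FALSE],
      seExposure = h@seExposure[keep, , drop = FALSE],
      nExposure = h@nExposure[keep, , drop = FALSE],
      betaOutcome = h@betaOutcome[keep],
      seOutcome = h@seOutcome[keep],
      nOutcome = h@nOutcome[keep],
      exposures = h@exposures, outcome = h@outcome, dropped = dropped)
}

#' Steiger directionality filter
#'
#' Per variant, the variance explained in the exposure is approximated by
#' `r2 = t^2 / (t^2 + n - 2)` with `t = beta/se`, and analogously in the
#' outcome (for a binary outcome this is the observation-scale
#' approximation from beta, se and n). Variants explaining strictly more
#' variance in the outcome than in the exposure are presumed
#' reverse-causal and dropped with reason `steiger_reverse`; ties are
#' retained.
#'
#' @param h a [HarmonizedSet-class] with per-variant sample sizes on both
#'   sides.
#' @return list with `filtered` (pruned [HarmonizedSet-class]), `r2Exposure`,
#'   `r2Outcome` (named vectors) and `removed` (variant ids).
#' @export
steigerFilter <- function(h) {
  .stopIfNot(nVariants(h) > 0, "empty harmonized set")
  nx <- h@nExposure[, 1]
  ny <- h@nOutcome
  .stopIfNot(!any(is.na(nx)) && !any(is.na(ny)),
             "per-variant sample sizes are required on both sides")
  tx <- h@betaExposure[, 1] / h@seExposure[, 1]
  ty <- h@betaOutcome / h@seOutcome
  r2x <- tx^2 / (tx^2 + nx - 2)
  r2y <- ty^2 / (ty^2 + ny - 2)
  names(r2x) <- names(r2y) <- h@variants$variant_id
  removed <- h@variants$variant_id[r2y > r2x]
  list(filtered = .dropVariants(h, removed, "steiger_reverse"),
       r2Exposure = r2x, r2Outcome = r2y, removed = removed)
}
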