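#' @include harmonize.R
NULL

#' Wald ratio estimate for a single variant
#'
#' The per-variant causal estimate beta_outcome / beta_exposure. The
#' default standard error is the first-order delta approximation
#' `|se_outcome / beta_exposure|`; `secondOrder = TRUE` adds the
#' exposure-uncertainty term
#' `sqrt(se_y^2/beta_x^2 + beta_y^2 se_x^2 / beta_x^4)`.
#'
#' @param betaX,seX exposure association and its standard error.
#' @param betaY,seY outcome association and its standard error.
#' @param secondOrder include the exposure-uncertainty term.
#' @param exposure,outcome trait labels.
#' @return an [MREstimate-class] with method `"wald"`.
#' @examples
#' waldRatio(0.1, 0.01, 0.05, 0.01)
#' @export
waldRatio <- function(betaX, seX, betaY, seY, secondOrder = FALSE,
                      exposure = "exposure", outcome = "outcome") {
  .stopIfNot(betaX != 0, "beta_exposure must be nonzero for a Wald ratio")
  est <- betaY / betaX
  se <- if (secondOrder) {
    sqrt(seY^2 / betaX^2 + betaY^2 * seX^2 / betaX^4)
  } else {
    abs(seY / betaX)
  }
  .newMREstimate("wald", exposure, outcome, est, se, nVariants = 1L)
}

#' Inverse-variance weighted estimate
#'
#' The precision-weighted average of per-variant Wald ratios with
#' first-order weights `w_j = beta_xj^2 / se_yj^2`, algebraically equal to
#' weighted least squares of outcome betas on exposure betas through the
#' origin with weights `1/se_yj^2`. The fixed-effect standard error is
#' `(sum w_j)^-1/2`; the multiplicative random-effects model (the default)
#' scales it by `max(1, sqrt(Q/(J-1)))` where Q is Cochran's heterogeneity
#' statistic. A single-variant set degrades to the Wald ratio with a
#' warning.
#'
#' @param h a [HarmonizedSet-class] (first exposure column is used).
#' @param model `"random"` (multiplicative random effects) or `"fixed"`.
#' @return an [MREstimate-class].
#' @export
mrIvw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  J <- nVariants(h)
  .stopIfNot(J >= 1, "empty harmonized set")
  x <- h@betaExposure[, 1]
  y <- h@betaOutcome
  sy <- h@seOutcome
  if (J == 1L) {
    warning("single variant: IVW degrades to the Wald ratio",
            call. = FALSE)
    out <- waldRatio(x, h@seExposure[, 1], y, sy,
                     exposure = h@exposures[1], outcome = h@outcome)
    return(out)
  }
  ratio <- y / x
  w <- x^2 / sy^2
  est <- sum(w * ratio) / sum(w)
  seFixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (ratio - est)^2)
  qP <- stats::pchisq(Q, df = J - 1, lower.tail = FALSE)
  se <- if (model == "fixed") seFixed
        else seFixed * max(1, sqrt(Q / (J - 1)))
  .newMREstimate(paste0("ivw_", model), h@exposures[1], h@outcome,
                 est, se, nVariants = J, q = Q, qP = qP)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas *with* an
#' intercept (weights `1/se_yj^2`), after orienting all variants so the
#' exposure betas are non-negative. The intercept estimates the average
#' directional (unbalanced) pleiotropy and its p-value is the pleiotropy
#' test; the slope is the pleiotropy-adjusted causal estimate. Standard
#' errors use the multiplicative random-effects scaling
#' `max(1, sqrt(RSS_w/(J-2)))`.
#'
#' @param h a [HarmonizedSet-class] with at least 3 variants.
#' @return list with elements `slope` and `intercept`, both
#'   [MREstimate-class].
#' @export
mrEgger <- function(h) {
  J <- nVariants(h)
  .stopIfNot(J >= 3, "MR-Egger requires at least 3 variants")
  x <- h@betaExposure[, 1]
  y <- h@betaOutcome
  flip <- sign(x)
  flip[flip == 0] <- 1
  x <- x * flip
  y <- y * flip
  w <- 1 / h@seOutcome^2
  fit <- .wlsOrigin(cbind(intercept = 1, slope = x), y, w)
  scale <- max(1, sqrt(fit$rssW / (J - 2)))
  ses <- sqrt(diag(fit$covUnscaled)) * scale
  qP <- stats::pchisq(fit$rssW, df = J - 2, lower.tail = FALSE)
  list(
    slope = .newMREstimate("egger_slope", h@exposures[1], h@outcome,
                           unname(fit$coef[2]), ses[2], nVariants = J,
                           q = fit$rssW, qP = qP),
    intercept = .newMREstimate("egger_intercept", h@exposures[1],
                               h@outcome, unname(fit$coef[1]), ses[1],
                               nVariants = J, q = fit$rssW, qP = qP)
  )
}

#' Per-variant and mean instrument strength
#'
#' The univariable F statistic per variant,
#' `F_j = (beta_exposure_j / se_exposure_j)^2`, and their mean. (The
#' conditional F for multivariable MR is computed by [mrMvmr()].)
#'
#' @param h a [HarmonizedSet-class] or [InstrumentSet-class].
#' @return list with `perVariant` (named vector) and `meanF`.
#' @export
instrumentStrength <- function(h) {
  if (is(h, "InstrumentSet")) {
    .stopIfNot(nrow(h@data) > 0, "empty instrument set")
    f <- (h@data$beta / h@data$standard_error)^2
    names(f) <- h@data$variant_id
  } else {
    .stopIfNot(nVariants(h) > 0, "empty harmonized set")
    f <- (h@betaExposure[, 1] / h@seExposure[, 1])^2
    names(f) <- h@variants$variant_id
  }
  list(perVariant = f, meanF = mean(f))
}
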