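#' @include mr-sensitivity.R
NULL

#' Multivariable Mendelian randomization
#'
#' Weighted multiple regression without intercept of the outcome betas on
#' the K exposure-beta columns (weights `1/se_outcome^2`), giving each
#' exposure's direct effect conditional on the others — the package's
#' device for estimating a mediator's effect on the outcome with
#' adjustment for the primary exposure. Standard errors use multiplicative
#' random-effects scaling `max(1, sqrt(RSS_w/(J-K)))`. Instrument strength
#' per exposure is the conditional F in the Sanderson-Windmeijer spirit:
#' exposure k's betas are regressed on the other exposures' betas (weights
#' `1/se_xk^2`, no intercept) and
#' `F_k = Q_k / (J - K + 1)` with `Q_k` the weighted residual sum of
#' squares; `F_k < 10` raises the weak-instrument flag. Exposure columns
#' that are identically zero are excluded from the fit (their estimate is
#' `NA`), so a multivariable fit with one informative column reduces to
#' the univariable IVW estimate; any other rank deficiency is an error.
#'
#' @param h a [HarmonizedSet-class] with K >= 2 exposure columns.
#' @param weakFThreshold conditional-F threshold below which an exposure
#'   is flagged weak.
#' @return named list of [MREstimate-class], one per exposure (method
#'   `"mvmr"`), each carrying its conditional F and weak-instrument flag.
#' @export
mrMvmr <- function(h, weakFThreshold = 10) {
  K <- ncol(h@betaExposure)
  J <- nVariants(h)
  .stopIfNot(K >= 2, "multivariable MR needs at least two exposures")
  .stopIfNot(J > K, "more variants than exposures are required")
  X <- h@betaExposure
  y <- h@betaOutcome
  w <- 1 / h@seOutcome^2
  zero <- apply(X, 2, function(col) all(abs(col) < 1e-12))
  Xf <- X[, !zero, drop = FALSE]
  Kf <- ncol(Xf)
  fit <- .wlsOrigin(Xf, y, w)
  scale <- max(1, sqrt(fit$rssW / (J - Kf)))
  ses <- sqrt(diag(fit$covUnscaled)) * scale
  qP <- stats::pchisq(fit$rssW, df = J - Kf, lower.tail = FALSE)
  out <- vector("list", K)
  names(out) <- colnames(X)
  fitIdx <- 0L
  for (k in seq_len(K)) {
    name <- colnames(X)[k]
    if (zero[k]) {
      out[[k]] <- .newMREstimate("mvmr", name, h@outcome, NA_real_,
                                 NA_real_, nVariants = J,
                                 conditionalF = 0, weak = TRUE)
      next
    }
    fitIdx <- fitIdx + 1L
    condF <- if (K > 1) {
      others <- X[, -k, drop = FALSE]
      others <- others[, apply(others, 2,
                               function(col) any(abs(col) > 1e-12)),
                       drop = FALSE]
      wk <- 1 / h@seExposure[, k]^2
      qk <- if (ncol(others) == 0L) {
        sum(wk * X[, k]^2)
      } else {
        .wlsOrigin(others, X[, k], wk)$rssW
      }
      qk / (J - K + 1)
    } else {
      NA_real_
    }
    out[[k]] <- .newMREstimate(
      "mvmr", name, h@outcome, unname(fit$coef[fitIdx]), ses[fitIdx],
      nVariants = J, q = fit$rssW, qP = qP, conditionalF = condF,
      weak = is.finite(condF) && condF < weakFThreshold)
  }
  out
}
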