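#' @include AllClasses.R
NULL

## Two-sided p from a normal z, the large-sample convention used throughout.
.z2p <- function(z) 2 * stats::pnorm(-abs(z))

.newMREstimate <- function(method, exposure, outcome, estimate, se,
                           nVariants, q = NA_real_, qP = NA_real_,
                           conditionalF = NA_real_, weak = NA) {
  z <- stats::qnorm(0.975)
  estimate <- unname(estimate)
  se <- unname(se)
  new("MREstimate", method = method, exposure = exposure, outcome = outcome,
      estimate = estimate, se = se, p = .z2p(estimate / se),
      ciLow = estimate - z * se, ciHigh = estimate + z * se,
      nVariants = as.integer(nVariants), qStatistic = q, qP = qP,
      conditionalF = conditionalF, weakInstrument = weak)
}

.newEffectEstimate <- function(term, estimate, se, scale, perSd,
                               adjustment = character(0), n = NA_integer_,
                               nEvents = NA_integer_, notes = character(0)) {
  new("EffectEstimate", term = term, estimate = estimate, se = se,
      p = .z2p(estimate / se), scale = scale, perSd = perSd,
      adjustment = adjustment, n = as.integer(n),
      nEvents = as.integer(nEvents), notes = notes)
}

## Weighted least squares without intercept via explicit QR on the scaled
## design; returns coefficients, the unscaled covariance (X'WX)^-1 and the
## weighted residual sum of squares.
.wlsOrigin <- function(X, y, w) {
  X <- as.matrix(X)
  sw <- sqrt(w)
  fit <- tryCatch(qr(X * sw), error = function(e) stop(e))
  if (fit$rank < ncol(X)) stop("rank-deficient design in weighted regression")
  coef <- qr.coef(fit, y * sw)
  res <- y - drop(X %*% coef)
  R <- qr.R(fit)
  covUnscaled <- chol2inv(R[seq_len(ncol(X)), , drop = FALSE])
  list(coef = coef, covUnscaled = covUnscaled, rssW = sum(w * res^2),
       residuals = res)
}

## Convert an MR estimate to the cohort currency so mediation code can
## consume either arm.
.asEffectEstimate <- function(mre, scale, term = mre@exposure) {
  .newEffectEstimate(term = term, estimate = mre@estimate, se = mre@se,
                     scale = scale, perSd = TRUE,
                     adjustment = if (mre@method == "mvmr")
                       setdiff(mre@exposure, term) else character(0),
                     notes = sprintf("mr:%s", mre@method))
}

.isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
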