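#' @include utils.R
#' @importFrom survival Surv strata coxph clogit
NULL

#' Trait transformations used in the direct-assessment arm
#'
#' Mediators are transformed before cohort modelling to match the scale of
#' the GWAS used in the genetic arm: `log` (natural log, strictly positive
#' input required), `inverse_normal_rank` (ranks mapped to normal
#' quantiles with the Blom offset c = 3/8 and average ranks for ties),
#' `zscore` (centred, unit variance) or `per_sd` (divided by the sample
#' standard deviation, not centred). The transformation applied is
#' recorded as an attribute for provenance.
#'
#' @param x numeric vector.
#' @param method transformation name.
#' @return transformed vector with attribute `"transform"`.
#' @examples
#' transformTrait(rlnorm(10), "log")
#' transformTrait(1:5, "inverse_normal_rank")
#' @export
transformTrait <- function(x, method = c("zscore", "log",
                                         "inverse_normal_rank",
                                         "per_sd")) {
  method <- match.arg(method)
  out <- switch(method,
    log = {
      .stopIfNot(all(x > 0), "log transform requires strictly positive values")
      log(x)
    },
    inverse_normal_rank = {
      c0 <- 3 / 8
      n <- length(x)
      stats::qnorm((rank(x, ties.method = "average") - c0) /
                     (n + 1 - 2 * c0))
    },
    zscore = (x - mean(x)) / stats::sd(x),
    per_sd = x / stats::sd(x)
  )
  attr(out, "transform") <- method
  out
}

#' Impute concentrations below the limit of detection
#'
#' Values strictly below the limit of detection are replaced by
#' LOD / sqrt(2); values at or above the limit are untouched. The number
#' of replacements is recorded as an attribute.
#'
#' @param x numeric vector of measured concentrations.
#' @param lod positive limit of detection.
#' @return vector with attribute `"nImputed"`.
#' @examples
#' imputeBelowLod(c(0.5, 1.9, 2.0, 3.1), lod = 2)
#' @export
imputeBelowLod <- function(x, lod) {
  .stopIfNot(lod > 0, "lod must be positive")
  below <- !is.na(x) & x < lod
  x[below] <- lod / sqrt(2)
  attr(x, "nImputed") <- sum(below)
  x
}

.buildFormula <- function(response, terms) {
  stats::reformulate(sprintf("`%s`", terms),
                     response = response, env = parent.frame())
}

#' Exposure-to-mediator linear model (a path)
#'
#' Linear regression of the (transformed) mediator on the exposure scaled
#' per sample standard deviation, with the stated adjustment set. Aliased
#' (collinear) covariates are reported in the estimate's notes.
#'
#' @param cohort cohort `data.frame`.
#' @param mediator response column (transform it first, see
#'   [transformTrait()]).
#' @param exposure exposure column (default `"bmi"`).
#' @param covariates adjustment columns (omit `sex` for sex-specific
#'   mediators).
#' @return an [EffectEstimate-class] for the per-SD exposure term, scale
#'   `"linear"`.
#' @export
apathLinear <- function(cohort, mediator, exposure = "bmi",
                        covariates = c("age", "sex", "center", "education",
                                       "smoking", "alcohol")) {
  df <- cohort
  df$.exposureSd <- df[[exposure]] / stats::sd(df[[exposure]])
  fml <- .buildFormula(mediator, c(".exposureSd", covariates))
  fit <- stats::lm(fml, data = df)
  cf <- summary(fit)$coefficients
  aliased <- names(which(is.na(stats::coef(fit))))
  notes <- if (length(aliased)) {
    sprintf("collinear covariates dropped: %s",
            paste(aliased, collapse = ", "))
  } else {
    character(0)
  }
  est <- cf[".exposureSd", ]
  .newEffectEstimate(term = exposure, estimate = unname(est["Estimate"]),
                     se = unname(est["Std. Error"]), scale = "linear",
                     perSd = TRUE, adjustment = covariates,
                     n = stats::nobs(fit), notes = notes)
}

#' Proportional-hazards risk model (b path and total effect)
#'
#' Cox regression of the survival outcome on the per-SD term with the
#' stated adjustment set, follow-up time as the underlying timescale and
#' Efron handling of ties. For the mediation b path, pass the exposure in
#' `extraAdjust`; for the total effect, model the exposure itself.
#'
#' @param cohort cohort `data.frame` with `followup_time` and `event`.
#' @param term modelled column.
#' @param covariates adjustment columns.
#' @param extraAdjust optional further column(s) (e.g. the exposure when
#'   the term is a mediator).
#' @param perSd scale the term per sample standard deviation.
#' @return an [EffectEstimate-class], scale `"log_hazard"`.
#' @export
coxRisk <- function(cohort, term,
                    covariates = c("age", "sex", "center", "education",
                                   "smoking", "alcohol"),
                    extraAdjust = NULL, perSd = TRUE) {
  .stopIfNot(all(cohort$followup_time > 0), "follow-up times must be positive")
  nEvents <- sum(cohort$event)
  .stopIfNot(nEvents >= 1, "no events in cohort")
  df <- cohort
  df$.termSd <- if (perSd) df[[term]] / stats::sd(df[[term]]) else df[[term]]
  rhs <- c(".termSd", covariates, extraAdjust)
  fml <- stats::as.formula(paste(
    "Surv(followup_time, event) ~",
    paste(sprintf("`%s`", rhs), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  cf <- summary(fit)$coefficients
  .newEffectEstimate(term = term,
                     estimate = unname(cf[".termSd", "coef"]),
                     se = unname(cf[".termSd", "se(coef)"]),
                     scale = "log_hazard", perSd = perSd,
                     adjustment = c(covariates, extraAdjust),
                     n = fit$n, nEvents = nEvents)
}

#' Conditional logistic regression on matched case-sets
#'
#' Conditional-likelihood log-odds for the term within matched sets (each
#' with exactly one case), the matched-design analogue of the Cox risk
#' model used for mediators measured in a nested case-control substudy.
#' Matched sets without within-set variation in the term contribute
#' nothing; when no set is informative the model is non-identified and an
#' `NA` estimate is returned with a flag in the notes.
#'
#' @param cohort matched `data.frame` with `event` and `matched_set`.
#' @param term modelled column.
#' @param perSd scale the term per sample standard deviation (use `FALSE`
#'   for, e.g., log-insulin modelled per log-unit).
#' @return an [EffectEstimate-class], scale `"log_odds"`.
#' @export
conditionalLogistic <- function(cohort, term, perSd = TRUE) {
  .stopIfNot("matched_set" %in% names(cohort),
             "cohort must carry matched_set labels")
  caseCount <- tapply(cohort$event, cohort$matched_set, sum)
  .stopIfNot(all(caseCount == 1L), "every matched set needs exactly one case")
  df <- cohort
  df$.termSd <- if (perSd) df[[term]] / stats::sd(df[[term]]) else df[[term]]
  varWithin <- tapply(df$.termSd, df$matched_set,
                      function(v) stats::var(v) > 0)
  if (!any(varWithin)) {
    return(.newEffectEstimate(term = term, estimate = NA_real_,
                              se = NA_real_, scale = "log_odds",
                              perSd = perSd, n = nrow(df),
                              nEvents = sum(df$event),
                              notes = "non-identified: no within-set variation"))
  }
  fit <- survival::clogit(event ~ .termSd + strata(matched_set), data = df)
  cf <- summary(fit)$coefficients
  .newEffectEstimate(term = term, estimate = unname(cf[1, "coef"]),
                     se = unname(cf[1, "se(coef)"]), scale = "log_odds",
                     perSd = perSd, n = nrow(df), nEvents = sum(df$event))
}
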