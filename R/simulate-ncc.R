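#' @include simulate-traits.R
NULL

#' Nested case-control sampling with incidence-density matching
#'
#' Builds matched case-control sets from a cohort: each case is paired with
#' `ratio` controls sampled without replacement from participants still at
#' risk at the case's event time (incidence-density sampling, so later
#' cases are eligible controls for earlier cases), satisfying exact
#' matching on the `exact` columns and the stated tolerances on numeric
#' columns. Controls are never reused across sets. Cases with no eligible
#' control are dropped with a warning and reported.
#'
#' @param cohort cohort `data.frame` with `followup_time` and `event`.
#' @param ratio controls per case.
#' @param exact character vector of columns matched exactly (default sex).
#' @param tolerances named list of absolute tolerances on numeric columns
#'   (default age within 0.5 years).
#' @return the matched rows with a `matched_set` label (case first within
#'   each set); unmatched case ids are in `attr(, "unmatched")`.
#' @examples
#' cfg <- simulationConfig(nIndividuals = 2000, nSnpsExposure = 5,
#'                         nMediators = 0, nSnpsMediator = 0,
#'                         baselineHazard = 0.01)
#' set.seed(7)
#' g <- simulateGenotypes(cfg, n = 2000)
#' sim <- simulateTraits(g$genotypes, g$panel, cfg)
#' ncc <- buildNestedCaseControl(sim$cohort)
#' table(table(ncc$matched_set))
#' @export
buildNestedCaseControl <- function(cohort, ratio = 1L,
                                   exact = "sex",
                                   tolerances = list(age = 0.5)) {
  .stopIfNot(any(cohort$event == 1L), "cohort contains no events")
  .stopIfNot(ratio >= 1L, "ratio must be at least 1")
  caseIdx <- which(cohort$event == 1L)
  caseIdx <- caseIdx[order(cohort$followup_time[caseIdx])]
  ## controls are sampled without replacement; a participant drawn as a
  ## control for an earlier case may still appear later as a case in their
  ## own set (they were event-free when sampled)
  usedCtrl <- rep(FALSE, nrow(cohort))
  sets <- list()
  unmatched <- character(0)
  setNo <- 0L
  for (ci in caseIdx) {
    t0 <- cohort$followup_time[ci]
    ok <- !usedCtrl & cohort$followup_time > t0
    for (col in exact) ok <- ok & cohort[[col]] == cohort[[col]][ci]
    for (col in names(tolerances)) {
      ok <- ok & abs(cohort[[col]] - cohort[[col]][ci]) <= tolerances[[col]]
    }
    ok[ci] <- FALSE
    pool <- which(ok)
    if (length(pool) < ratio) {
      unmatched <- c(unmatched, cohort$id[ci])
      next
    }
    ctrl <- if (length(pool) == 1L) pool else sample(pool, ratio)
    setNo <- setNo + 1L
    usedCtrl[ctrl] <- TRUE
    sets[[setNo]] <- c(ci, ctrl)
  }
  if (length(unmatched)) {
    warning(sprintf("%d case(s) had no eligible control and were dropped",
                    length(unmatched)), call. = FALSE)
  }
  if (!setNo) {
    out <- cohort[0, , drop = FALSE]
    out$matched_set <- character(0)
    attr(out, "unmatched") <- unmatched
    return(out)
  }
  rows <- unlist(sets)
  out <- cohort[rows, , drop = FALSE]
  out$matched_set <- rep(sprintf("set%04d", seq_len(setNo)),
                         each = ratio + 1L)
  ## the sampled "control" copy of a later case enters the set event-free
  out$event <- rep(c(1L, rep(0L, ratio)), setNo)
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}
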