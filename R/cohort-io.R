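#' @include simulate-traits.R
NULL

.COHORT_REQUIRED <- c("id", "followup_time", "event")

#' Read and write cohort tables
#'
#' The cohort table is plain CSV with one row per participant and a
#' documented header: `id`, the covariates (`age`, `sex`, `center`,
#' `education`, `smoking`, `alcohol`), the exposure (`bmi`), one column
#' per mediator, `followup_time` (years, positive), `event` (0/1) and
#' optionally `matched_set`. `readCohort()` validates the survival
#' columns and re-levels the categorical covariates.
#'
#' @param path file path.
#' @return `readCohort()`: a validated `data.frame`; `writeCohort()`:
#'   the path, invisibly.
#' @export
readCohort <- function(path) {
  .stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.COHORT_REQUIRED, names(df))
  if (length(missing)) {
    stop(sprintf("cohort table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  .stopIfNot(all(df$followup_time > 0), "followup_time must be positive")
  .stopIfNot(all(df$event %in% c(0L, 1L)), "event must be 0/1")
  for (col in intersect(c("center", "education"), names(df))) {
    df[[col]] <- factor(df[[col]])
  }
  for (col in intersect(c("smoking", "alcohol"), names(df))) {
    df[[col]] <- factor(df[[col]],
                        levels = c("never", "former", "current"))
  }
  df
}

#' @rdname readCohort
#' @param cohort cohort `data.frame`.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
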