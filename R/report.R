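#' @include config.R mediation.R triangulate.R
NULL

.effectRow <- function(ee, framework, role, term = ee@term) {
  data.frame(
    term = term, framework = framework, role = role,
    beta = ee@estimate, se = ee@se,
    rr = if (ee@scale == "linear") NA_real_ else exp(ee@estimate),
    ci_low = ee@estimate - stats::qnorm(0.975) * ee@se,
    ci_high = ee@estimate + stats::qnorm(0.975) * ee@se,
    p = ee@p, scale = ee@scale, per_sd = ee@perSd,
    adjustment = paste(ee@adjustment, collapse = "+"),
    n = ee@n, n_events = ee@nEvents, n_variants = NA_integer_,
    q = NA_real_, q_p = NA_real_, stringsAsFactors = FALSE)
}

.mreRow <- function(mre, framework, role, term = mre@exposure) {
  data.frame(
    term = term, framework = framework, role = role,
    beta = mre@estimate, se = mre@se, rr = exp(mre@estimate),
    ci_low = mre@ciLow, ci_high = mre@ciHigh, p = mre@p,
    scale = "log_odds", per_sd = TRUE,
    adjustment = if (mre@method == "mvmr") "mvmr" else "",
    n = NA_integer_, n_events = NA_integer_, n_variants = mre@nVariants,
    q = mre@qStatistic, q_p = mre@qP, stringsAsFactors = FALSE)
}

.mediationRow <- function(mr) {
  data.frame(
    framework = mr@framework, mediator = mr@mediator,
    total_beta = mr@total@estimate, total_se = mr@total@se,
    direct_adjusted_beta = mr@directAdjusted@estimate,
    direct_difference = mr@directDifference,
    a_beta = mr@aPath@estimate, a_se = mr@aPath@se,
    b_beta = mr@bPath@estimate, b_se = mr@bPath@se,
    indirect_beta = mr@indirectBeta, indirect_se = mr@indirectSe,
    indirect_ci_low = mr@indirectCi[1], indirect_ci_high = mr@indirectCi[2],
    proportion_mediated = mr@proportionMediated,
    pm_ci_low = mr@pmCi[1], pm_ci_high = mr@pmCi[2],
    pm_out_of_range = mr@pmOutOfRange,
    weak_instrument = mr@weakInstrument,
    notes = paste(mr@methodNotes, collapse = "; "),
    stringsAsFactors = FALSE)
}

.triangulationRow <- function(tr) {
  data.frame(
    mediator = tr@mediator,
    cohort_beta = tr@cohortEstimate@estimate,
    cohort_p = tr@cohortEstimate@p,
    mr_beta = tr@mrEstimate@estimate, mr_p = tr@mrEstimate@p,
    directionally_concordant = tr@directionallyConcordant,
    both_significant = tr@bothSignificant, alpha = tr@alpha,
    eligible = tr@eligible, pleiotropy_flag = tr@pleiotropyFlag,
    stringsAsFactors = FALSE)
}

#' Write the pipeline result bundle to disk
#'
#' Emits the tab-delimited tables (a-path, risk, triangulation, mediation,
#' pairwise edges, reason-coded dropped variants) with deterministic
#' column order and fixed significant digits, a machine-readable
#' `summary.json` at full precision, and a run manifest. An empty eligible
#' set yields a header-only mediation table.
#'
#' @param bundle result list from [runPipeline()].
#' @param dir output directory (created if needed).
#' @param digits significant digits for the human-readable tables.
#' @return invisible character vector of files written.
#' @export
writeTables <- function(bundle, dir, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    for (col in names(df)) {
      if (is.numeric(df[[col]])) df[[col]] <- signif(df[[col]], digits)
    }
    df
  }
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(fmt(df), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, p)
  }
  wr(bundle$apath, "apath.tsv")
  wr(bundle$risk, "risk.tsv")
  wr(bundle$triangulation, "triangulation.tsv")
  wr(bundle$mediation, "mediation.tsv")
  if (!is.null(bundle$edges)) wr(bundle$edges, "edges.tsv")
  if (!is.null(bundle$droppedVariants)) {
    wr(bundle$droppedVariants, "dropped_variants.tsv")
  }
  summary <- list(
    seed = bundle$config$seed,
    counts = bundle$counts,
    arm_concordance_r2 = bundle$armConcordanceR2,
    ground_truth = if (!is.null(bundle$groundTruth)) list(
      total = bundle$groundTruth@totalLogEffect,
      direct = bundle$groundTruth@directLogEffect,
      indirect = bundle$groundTruth@indirectLogEffect,
      proportion_mediated = bundle$groundTruth@proportionMediated),
    apath = bundle$apath, risk = bundle$risk,
    triangulation = bundle$triangulation, mediation = bundle$mediation)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       na = "null")
  files <- c(files, p)
  mf <- runManifest(bundle$config, files)
  pm <- file.path(dir, "manifest.json")
  jsonlite::write_json(mf, pm, auto_unbox = TRUE, digits = NA)
  invisible(c(files, pm))
}

#' Run manifest
#'
#' Records what is needed to reproduce a run byte-identically: the seed,
#' a hash of the normalized configuration, package version, timestamp and
#' md5 checksums of every output file.
#'
#' @param config configuration list.
#' @param files output files to checksum.
#' @return manifest list.
#' @export
runManifest <- function(config, files = character(0)) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("trimediate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    checksums = as.list(tools::md5sum(files))
  )
}
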