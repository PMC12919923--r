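#' @include AllClasses.R utils.R
NULL

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-delimited (GWAS-SSF-like) summary-statistics file into a
#' validated [GwasSumstats-class]. Columns may be renamed through
#' `columnMap`; alleles are upper-cased. Malformed rows — non-numeric or
#' missing beta/standard error, non-positive standard error, p outside
#' (0, 1], allele frequency outside (0, 1), alleles that are not single
#' A/C/G/T bases — are dropped, counted and reported; rows whose p-value
#' disagrees with the normal approximation `(beta/se)^2` by more than 10%
#' on the z scale are kept but counted as inconsistent.
#'
#' @param path file path.
#' @param columnMap named character vector mapping canonical names to the
#'   file's column names, e.g. `c(beta = "b", standard_error = "se")`.
#' @param trait trait label.
#' @param sep field separator.
#' @return a [GwasSumstats-class]; counts of rejected rows per reason are
#'   in `attr(, "rejected")`, inconsistent-p count in
#'   `attr(, "inconsistentP")`.
#' @export
readSumstats <- function(path, columnMap = NULL, trait = "trait",
                         sep = "\t") {
  .stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (!is.null(columnMap)) {
    for (canon in names(columnMap)) {
      names(raw)[names(raw) == columnMap[[canon]]] <- canon
    }
  }
  missing <- setdiff(.SUMSTATS_COLS, names(raw))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  raw <- raw[.SUMSTATS_COLS]
  for (col in c("base_pair_location", "effect_allele_frequency", "beta",
                "standard_error", "p_value", "n")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  raw$effect_allele <- toupper(raw$effect_allele)
  raw$other_allele <- toupper(raw$other_allele)

  rejected <- c(non_numeric = 0L, se_not_positive = 0L, bad_p = 0L,
                bad_eaf = 0L, bad_allele = 0L)
  ok <- rep(TRUE, nrow(raw))
  bad <- is.na(raw$beta) | is.na(raw$standard_error) |
    is.na(raw$p_value) | is.na(raw$n) | is.na(raw$effect_allele_frequency)
  rejected["non_numeric"] <- sum(bad)
  ok <- ok & !bad
  bad <- ok & raw$standard_error <= 0
  rejected["se_not_positive"] <- sum(bad); ok <- ok & !bad
  bad <- ok & (raw$p_value <= 0 | raw$p_value > 1)
  rejected["bad_p"] <- sum(bad); ok <- ok & !bad
  bad <- ok & (raw$effect_allele_frequency <= 0 |
                 raw$effect_allele_frequency >= 1)
  rejected["bad_eaf"] <- sum(bad); ok <- ok & !bad
  bases <- c("A", "C", "G", "T")
  bad <- ok & (!raw$effect_allele %in% bases | !raw$other_allele %in% bases |
                 raw$effect_allele == raw$other_allele)
  rejected["bad_allele"] <- sum(bad); ok <- ok & !bad
  df <- raw[ok, , drop = FALSE]
  rownames(df) <- NULL
  zFromP <- stats::qnorm(pmax(df$p_value, 1e-300) / 2, lower.tail = FALSE)
  zObs <- abs(df$beta / df$standard_error)
  inconsistent <- sum(abs(zFromP - zObs) > 0.1 * pmax(zObs, 1), na.rm = TRUE)
  if (sum(rejected) > 0) {
    message(sprintf("dropped %d malformed row(s): %s", sum(rejected),
                    paste(sprintf("%s=%d", names(rejected), rejected),
                          collapse = ", ")))
  }
  out <- new("GwasSumstats", data = df, trait = trait)
  attr(out, "rejected") <- rejected
  attr(out, "inconsistentP") <- inconsistent
  out
}

#' Write GWAS summary statistics
#'
#' Writes the canonical tab-delimited layout; a round trip through
#' [readSumstats()] reproduces the object.
#'
#' @param object a [GwasSumstats-class] or [InstrumentSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(object, path) {
  df <- if (is(object, "GwasSumstats")) object@data else object@data
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Three-column delimited text: `id_a`, `id_b`, `r2`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return `data.frame` with columns `id_a`, `id_b`, `r2`.
#' @export
readLdTable <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  .stopIfNot(all(c("id_a", "id_b", "r2") %in% names(df)),
             "LD table needs columns id_a, id_b, r2")
  df$r2 <- as.numeric(df$r2)
  df
}
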