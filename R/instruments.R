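#' @include sumstats-io.R
NULL

#' Select genetic instruments by significance filtering and LD clumping
#'
#' Excludes variants that are not genome-wide significant
#' (p > `pThreshold`, default 5e-8) and prunes correlated variants by
#' greedy clumping: candidates are sorted by ascending p-value (ties broken
#' by chromosome, position, then identifier, for determinism); the best
#' remaining variant is accepted and every same-chromosome variant within
#' `windowKb` whose LD r-squared with it exceeds `r2Threshold` (default
#' 0.01, window 10,000 kb) is discarded; this repeats until the candidate
#' list is exhausted. LD that is missing for a pair within the window is
#' treated as r2 = 1, so possibly-correlated variants are never retained
#' together. Pairs farther apart than the window are always retained,
#' whatever their LD.
#'
#' @param sumstats a [GwasSumstats-class].
#' @param pThreshold significance threshold.
#' @param ld pairwise LD as a `data.frame` (`id_a`, `id_b`, `r2`), e.g.
#'   from [ldFromGenotypes()] or [readLdTable()]; `NULL` means no LD is
#'   known (every within-window pair is pruned).
#' @param r2Threshold LD pruning threshold.
#' @param windowKb clumping window in kilobases.
#' @return an [InstrumentSet-class]; an empty result is signalled with a
#'   warning of class `trimediate_empty_instruments`, not an error.
#' @export
selectInstruments <- function(sumstats, pThreshold = 5e-8, ld = NULL,
                              r2Threshold = 0.01, windowKb = 10000) {
  df <- sumstats@data
  cand <- df[df$p_value <= pThreshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    w <- simpleWarning("no variant passes the significance threshold")
    class(w) <- c("trimediate_empty_instruments", class(w))
    warning(w)
    return(new("InstrumentSet", data = cand, exposure = sumstats@trait,
               pThreshold = pThreshold, r2Threshold = r2Threshold,
               windowKb = windowKb))
  }
  ord <- order(cand$p_value, cand$chromosome, cand$base_pair_location,
               cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  ldKey <- if (!is.null(ld) && nrow(ld)) {
    stats::setNames(c(ld$r2, ld$r2),
                    c(paste(ld$id_a, ld$id_b), paste(ld$id_b, ld$id_a)))
  } else {
    numeric(0)
  }
  alive <- rep(TRUE, nrow(cand))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive &
                    cand$chromosome == cand$chromosome[i] &
                    abs(cand$base_pair_location -
                          cand$base_pair_location[i]) < windowKb * 1000)
    if (!length(near)) next
    r2 <- ldKey[paste(cand$variant_id[i], cand$variant_id[near])]
    r2[is.na(r2)] <- 1      # unknown LD within the window: assume linked
    alive[near[r2 > r2Threshold]] <- FALSE
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$chromosome, out$base_pair_location,
                   out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  new("InstrumentSet", data = out, exposure = sumstats@trait,
      pThreshold = pThreshold, r2Threshold = r2Threshold,
      windowKb = windowKb)
}

#' Merge instrument sets for multivariable MR
#'
#' Takes the union of several exposures' instruments and re-applies greedy
#' clumping across the combined set (using each variant's smallest p-value
#' across the contributing exposures), so the joint instruments are
#' approximately independent.
#'
#' @param instrumentSets list of [InstrumentSet-class] objects.
#' @param ld pairwise LD table (see [selectInstruments()]).
#' @return an [InstrumentSet-class] labelled with the joined exposure
#'   names; thresholds are taken from the first set.
#' @export
unionInstruments <- function(instrumentSets, ld = NULL) {
  .stopIfNot(length(instrumentSets) >= 1, "need at least one instrument set")
  all <- do.call(rbind, lapply(instrumentSets, function(s) s@data))
  ## smallest p per variant across exposures
  ord <- order(all$variant_id, all$p_value)
  all <- all[ord, , drop = FALSE]
  all <- all[!duplicated(all$variant_id), , drop = FALSE]
  first <- instrumentSets[[1]]
  ss <- new("GwasSumstats", data = all,
            trait = paste(vapply(instrumentSets, function(s) s@exposure,
                                 character(1)), collapse = "+"))
  sel <- selectInstruments(ss, pThreshold = max(all$p_value), ld = ld,
                           r2Threshold = first@r2Threshold,
                           windowKb = first@windowKb)
  new("InstrumentSet", data = sel@data, exposure = ss@trait,
      pThreshold = first@pThreshold, r2Threshold = first@r2Threshold,
      windowKb = first@windowKb)
}
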