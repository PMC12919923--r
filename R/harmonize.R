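#' @include instruments.R
NULL

## Align target records to the reference effect/other alleles.
## Returns per-variant status ("aligned", "swapped", "mismatch") plus the
## target beta and eaf expressed relative to the reference effect allele.
.alignRecords <- function(refEA, refOA, tgtEA, tgtOA, tgtBeta, tgtEaf) {
  status <- rep("mismatch", length(refEA))
  status[tgtEA == refEA & tgtOA == refOA] <- "aligned"
  status[tgtEA == refOA & tgtOA == refEA] <- "swapped"
  beta <- ifelse(status == "swapped", -tgtBeta, tgtBeta)
  eaf <- ifelse(status == "swapped", 1 - tgtEaf, tgtEaf)
  list(status = status, beta = beta, eaf = eaf)
}

.emptyDropped <- function() {
  data.frame(variant_id = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns outcome records onto the exposure's effect allele so every
#' retained (beta_exposure, beta_outcome) pair refers to the same allele:
#' when the outcome alleles are swapped relative to the exposure, the
#' outcome beta sign is flipped and its allele frequency complemented;
#' records with incompatible alleles are dropped (`allele_mismatch`), as
#' are variants absent from the outcome (`missing_in_outcome`).
#' Palindromic variants (A/T or C/G) are retained only when both allele
#' frequencies fall outside the ambiguous zone
#' `[0.5 - palindromicWindow, 0.5 + palindromicWindow]` *and* the two
#' frequencies lie on the same side of 0.5 after alignment (a strand
#' check); otherwise they are dropped (`palindromic_ambiguous`).
#' Harmonization is idempotent: re-harmonizing an already-aligned pair
#' changes nothing.
#'
#' @param instruments an [InstrumentSet-class] (or [GwasSumstats-class])
#'   for the exposure.
#' @param outcome a [GwasSumstats-class] for the outcome.
#' @param palindromicWindow half-width of the ambiguous allele-frequency
#'   zone (default 0.08, i.e. 0.42-0.58).
#' @return a [HarmonizedSet-class] with one exposure column.
#' @export
harmonize <- function(instruments, outcome, palindromicWindow = 0.08) {
  exp <- if (is(instruments, "InstrumentSet")) instruments@data
         else instruments@data
  expName <- if (is(instruments, "InstrumentSet")) instruments@exposure
             else instruments@trait
  out <- outcome@data
  if (anyDuplicated(exp$variant_id)) {
    stop("duplicate variant identifiers in exposure", call. = FALSE)
  }
  if (anyDuplicated(out$variant_id)) {
    stop("duplicate variant identifiers in outcome", call. = FALSE)
  }
  idx <- match(exp$variant_id, out$variant_id)
  dropped <- .emptyDropped()
  miss <- is.na(idx)
  if (any(miss)) {
    dropped <- rbind(dropped, data.frame(
      variant_id = exp$variant_id[miss], reason = "missing_in_outcome",
      stringsAsFactors = FALSE))
  }
  exp2 <- exp[!miss, , drop = FALSE]
  out2 <- out[idx[!miss], , drop = FALSE]
  al <- .alignRecords(exp2$effect_allele, exp2$other_allele,
                      out2$effect_allele, out2$other_allele,
                      out2$beta, out2$effect_allele_frequency)
  keep <- al$status != "mismatch"
  reason <- rep(NA_character_, nrow(exp2))
  reason[!keep] <- "allele_mismatch"
  pal <- .isPalindromic(exp2$effect_allele, exp2$other_allele)
  w <- palindromicWindow
  ambiguous <- pal & keep &
    (abs(exp2$effect_allele_frequency - 0.5) <= w |
       abs(al$eaf - 0.5) <= w |
       sign(exp2$effect_allele_frequency - 0.5) != sign(al$eaf - 0.5))
  reason[ambiguous] <- "palindromic_ambiguous"
  keep <- keep & !ambiguous
  if (any(!keep)) {
    dropped <- rbind(dropped, data.frame(
      variant_id = exp2$variant_id[!keep], reason = reason[!keep],
      stringsAsFactors = FALSE))
  }
  exp3 <- exp2[keep, , drop = FALSE]
  variants <- data.frame(
    variant_id = exp3$variant_id,
    chromosome = exp3$chromosome,
    base_pair_location = exp3$base_pair_location,
    effect_allele = exp3$effect_allele,
    other_allele = exp3$other_allele,
    eaf_exposure = exp3$effect_allele_frequency,
    eaf_outcome = al$eaf[keep],
    stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  new("HarmonizedSet",
      variants = variants,
      betaExposure = matrix(exp3$beta, ncol = 1,
                            dimnames = list(NULL, expName)),
      seExposure = matrix(exp3$standard_error, ncol = 1,
                          dimnames = list(NULL, expName)),
      nExposure = matrix(exp3$n, ncol = 1,
                         dimnames = list(NULL, expName)),
      betaOutcome = unname(al$beta[keep]),
      seOutcome = out2$standard_error[keep],
      nOutcome = out2$n[keep],
      exposures = expName, outcome = outcome@trait,
      dropped = dropped)
}

#' Harmonize several exposures with an outcome (multivariable MR input)
#'
#' Starting from a joint instrument list (see [unionInstruments()]), looks
#' up each variant's effect in every exposure's full summary statistics and
#' in the outcome, aligning all of them to the instrument list's effect
#' allele with the same rules as [harmonize()]. Variants absent from any
#' exposure are dropped with reason `missing_in_exposure`.
#'
#' @param instruments an [InstrumentSet-class] with the joint instruments.
#' @param exposureList named list of [GwasSumstats-class], one per
#'   exposure, in the desired column order.
#' @param outcome a [GwasSumstats-class].
#' @param palindromicWindow as in [harmonize()].
#' @return a [HarmonizedSet-class] with K exposure columns.
#' @export
harmonizeMulti <- function(instruments, exposureList, outcome,
                           palindromicWindow = 0.08) {
  .stopIfNot(length(names(exposureList)) == length(exposureList) &&
               !any(names(exposureList) == ""),
             "exposureList must be a named list")
  ref <- instruments@data
  if (anyDuplicated(ref$variant_id)) {
    stop("duplicate variant identifiers in instruments", call. = FALSE)
  }
  K <- length(exposureList)
  J0 <- nrow(ref)
  keep <- rep(TRUE, J0)
  reason <- rep(NA_character_, J0)
  betaX <- seX <- nX <- matrix(NA_real_, J0, K,
                               dimnames = list(NULL, names(exposureList)))
  for (k in seq_len(K)) {
    ss <- exposureList[[k]]@data
    if (anyDuplicated(ss$variant_id)) {
      stop(sprintf("duplicate variant identifiers in exposure '%s'",
                   names(exposureList)[k]), call. = FALSE)
    }
    idx <- match(ref$variant_id, ss$variant_id)
    miss <- is.na(idx)
    newDrop <- keep & miss & is.na(reason)
    reason[newDrop] <- "missing_in_exposure"
    keep <- keep & !miss
    ok <- which(!miss)
    al <- .alignRecords(ref$effect_allele[ok], ref$other_allele[ok],
                        ss$effect_allele[idx[ok]], ss$other_allele[idx[ok]],
                        ss$beta[idx[ok]],
                        ss$effect_allele_frequency[idx[ok]])
    mm <- ok[al$status == "mismatch"]
    reason[mm[keep[mm] & is.na(reason[mm])]] <- "allele_mismatch"
    keep[mm] <- FALSE
    betaX[ok, k] <- al$beta
    seX[ok, k] <- ss$standard_error[idx[ok]]
    nX[ok, k] <- ss$n[idx[ok]]
  }
  ## outcome alignment including the palindromic rule
  h1 <- harmonize(new("InstrumentSet", data = ref,
                      exposure = instruments@exposure,
                      pThreshold = instruments@pThreshold,
                      r2Threshold = instruments@r2Threshold,
                      windowKb = instruments@windowKb),
                  outcome, palindromicWindow = palindromicWindow)
  inOutcome <- ref$variant_id %in% h1@variants$variant_id
  d1 <- h1@dropped
  for (i in which(!inOutcome)) {
    if (keep[i] && is.na(reason[i])) {
      reason[i] <- d1$reason[match(ref$variant_id[i], d1$variant_id)]
    }
  }
  keep <- keep & inOutcome
  dropped <- data.frame(variant_id = ref$variant_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  oIdx <- match(ref$variant_id[keep], h1@variants$variant_id)
  variants <- h1@variants[oIdx, , drop = FALSE]
  rownames(variants) <- NULL
  new("HarmonizedSet",
      variants = variants,
      betaExposure = betaX[keep, , drop = FALSE],
      seExposure = seX[keep, , drop = FALSE],
      nExposure = nX[keep, , drop = FALSE],
      betaOutcome = h1@betaOutcome[oIdx],
      seOutcome = h1@seOutcome[oIdx],
      nOutcome = h1@nOutcome[oIdx],
      exposures = names(exposureList), outcome = outcome@trait,
      dropped = dropped)
}
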