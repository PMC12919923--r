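# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

.bases <- c("A", "C", "G", "T")

# A sumstats table from parallel vectors, with sensible defaults.
makeSumstatsData <- function(beta, se,
                             id = sprintf("rs%04d", seq_along(beta)),
                             chrom = rep("1", length(beta)),
                             pos = seq_along(beta) * 1e6,
                             ea = rep("A", length(beta)),
                             oa = rep("G", length(beta)),
                             eaf = rep(0.3, length(beta)),
                             n = rep(5e4, length(beta)),
                             p = NULL) {
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  data.frame(variant_id = id, chromosome = chrom,
             base_pair_location = pos, effect_allele = ea,
             other_allele = oa, effect_allele_frequency = eaf,
             beta = beta, standard_error = se,
             p_value = pmax(p, 1e-300), n = n,
             stringsAsFactors = FALSE)
}

makeSumstats <- function(..., trait = "trait") {
  new("GwasSumstats", data = makeSumstatsData(...), trait = trait)
}

# A harmonized set straight from effect vectors (K = 1).
makeHarmonized <- function(bx, sx, by, sy,
                           nx = rep(5e4, length(bx)),
                           ny = rep(5e4, length(bx)),
                           exposure = "x", outcome = "y") {
  J <- length(bx)
  variants <- data.frame(
    variant_id = sprintf("rs%04d", seq_len(J)),
    chromosome = rep("1", J), base_pair_location = seq_len(J) * 1e6,
    effect_allele = rep("A", J), other_allele = rep("G", J),
    eaf_exposure = rep(0.3, J), eaf_outcome = rep(0.3, J),
    stringsAsFactors = FALSE)
  new("HarmonizedSet", variants = variants,
      betaExposure = matrix(bx, ncol = 1, dimnames = list(NULL, exposure)),
      seExposure = matrix(sx, ncol = 1, dimnames = list(NULL, exposure)),
      nExposure = matrix(nx, ncol = 1, dimnames = list(NULL, exposure)),
      betaOutcome = by, seOutcome = sy, nOutcome = ny,
      exposures = exposure, outcome = outcome,
      dropped = data.frame(variant_id = character(0),
                           reason = character(0),
                           stringsAsFactors = FALSE))
}

# Random instrument-shaped harmonized sets for oracle-equivalence loops.
randomHarmonized <- function(J, slope = 0.3) {
  bx <- rnorm(J, 0.08, 0.02) * sample(c(-1, 1), J, replace = TRUE)
  sx <- runif(J, 0.005, 0.02)
  sy <- runif(J, 0.02, 0.08)
  by <- slope * bx + rnorm(J, 0, sy)
  makeHarmonized(bx, sx, by, sy)
}

# An effect estimate without fitting anything.
makeEffect <- function(estimate, se, scale = "log_hazard", term = "term",
                       perSd = TRUE) {
  new("EffectEstimate", term = term, estimate = estimate, se = se,
      p = 2 * pnorm(-abs(estimate / se)), scale = scale, perSd = perSd,
      adjustment = character(0), n = NA_integer_, nEvents = NA_integer_,
      notes = character(0))
}

makeMrEstimate <- function(estimate, se, method = "ivw_random",
                           nVariants = 10L) {
  z <- qnorm(0.975)
  new("MREstimate", method = method, exposure = "x", outcome = "y",
      estimate = estimate, se = se, p = 2 * pnorm(-abs(estimate / se)),
      ciLow = estimate - z * se, ciHigh = estimate + z * se,
      nVariants = as.integer(nVariants), qStatistic = NA_real_,
      qP = NA_real_, conditionalF = NA_real_, weakInstrument = NA)
}

# Independent brute-force greedy clumping oracle (quadratic scan).
bruteForceClump <- function(df, ld, r2max = 0.01, windowKb = 10000) {
  key <- paste(c(ld$id_a, ld$id_b), c(ld$id_b, ld$id_a))
  r2 <- setNames(c(ld$r2, ld$r2), key)
  df <- df[order(df$p_value, df$chromosome, df$base_pair_location,
                 df$variant_id), ]
  kept <- character(0)
  removed <- character(0)
  for (i in seq_len(nrow(df))) {
    v <- df$variant_id[i]
    if (v %in% removed) next
    kept <- c(kept, v)
    for (j in seq_len(nrow(df))) {
      u <- df$variant_id[j]
      if (u == v || u %in% removed || u %in% kept) next
      if (df$chromosome[j] != df$chromosome[i]) next
      if (abs(df$base_pair_location[j] - df$base_pair_location[i]) >=
            windowKb * 1000) next
      r <- r2[paste(v, u)]
      if (is.na(r)) r <- 1
      if (r > r2max) removed <- c(removed, u)
    }
  }
  sort(kept)
}

# Random allele recoding of sumstats rows: swap alleles, negate beta,
# complement the allele frequency. The association itself is unchanged.
recodeAlleles <- function(ss, which) {
  df <- ss@data
  ea <- df$effect_allele[which]
  df$effect_allele[which] <- df$other_allele[which]
  df$other_allele[which] <- ea
  df$beta[which] <- -df$beta[which]
  df$effect_allele_frequency[which] <-
    1 - df$effect_allele_frequency[which]
  new("GwasSumstats", data = df, trait = ss@trait)
}

# A small, fast study configuration for pipeline-level tests.
smallConfig <- function(...) {
  simulationConfig(nIndividuals = 4000, gwasNExposureArm = 6000,
                   gwasNOutcomeArm = 6000, nSnpsExposure = 12,
                   nSnpsMediator = 8, baselineHazard = 8e-3, ...)
}
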