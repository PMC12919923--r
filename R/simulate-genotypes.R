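#' @include AllClasses.R utils.R
NULL

#' Create a simulation configuration
#'
#' Returns a validated [SimulationConfig-class]. Defaults describe the study
#' conditions the package is designed around: a cohort of 100,000 with a
#' rare time-to-event outcome (roughly 1,400 events over 12 years of
#' follow-up, matching the event yield of a large population cohort), 50
#' independent exposure instruments explaining 10% of exposure variance,
#' one mediator downstream of the exposure, an unmeasured confounder, and
#' two non-overlapping GWAS arms of 50,000 each.
#'
#' @param seed RNG seed used by [simulateStudy()].
#' @param nIndividuals cohort size.
#' @param nSnpsExposure,nSnpsMediator instrument counts (`nSnpsMediator`
#'   per mediator).
#' @param nMediators number of mediators.
#' @param mediatorNames mediator names (defaults to `med1`, `med2`, ...).
#' @param mafRange allele-frequency range, within (0.01, 0.5].
#' @param ldBlockSize,ldRho,ldStructure LD-block structure; `ldRho` is the
#'   adjacent-variant genotype correlation.
#' @param h2Exposure,h2Mediator genetic variance fractions.
#' @param betaXM,betaMY,betaMM,betaXYdirect structural effects (see
#'   [SimulationConfig-class]).
#' @param confounderStrength loading of the latent confounder on exposure,
#'   mediators and log-hazard.
#' @param ageEffectExposure,ageEffectHazard,sexEffectHazard measured
#'   covariate loadings.
#' @param baselineHazard events per person-year at the linear-predictor
#'   origin.
#' @param followupYears administrative censoring time.
#' @param gwasNExposureArm,gwasNOutcomeArm GWAS arm sizes.
#' @param effectDistribution per-variant effect-size distribution,
#'   `"normal"` or `"equal"` (see [SimulationConfig-class]).
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nIndividuals = 2000, gwasNExposureArm = 2000,
#'                         gwasNOutcomeArm = 2000)
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             nIndividuals = 1e5,
                             nSnpsExposure = 50,
                             nSnpsMediator = 25,
                             nMediators = 1,
                             mediatorNames = NULL,
                             mafRange = c(0.05, 0.5),
                             ldBlockSize = 1,
                             ldRho = 0,
                             ldStructure = c("ar1", "exchangeable"),
                             h2Exposure = 0.10,
                             h2Mediator = 0.10,
                             betaXM = rep(0.5, nMediators),
                             betaMY = rep(0.4, nMediators),
                             betaMM = 0,
                             betaXYdirect = 0.2,
                             confounderStrength = 0.2,
                             ageEffectExposure = 0.1,
                             ageEffectHazard = 0.3,
                             sexEffectHazard = log(2),
                             baselineHazard = 8.46e-4,
                             followupYears = 12,
                             gwasNExposureArm = 5e4,
                             gwasNOutcomeArm = 5e4,
                             effectDistribution = c("normal", "equal")) {
  ldStructure <- match.arg(ldStructure)
  effectDistribution <- match.arg(effectDistribution)
  if (is.null(mediatorNames)) {
    mediatorNames <- if (nMediators > 0) paste0("med", seq_len(nMediators))
                     else character(0)
  }
  new("SimulationConfig", seed = seed, nIndividuals = nIndividuals,
      nSnpsExposure = nSnpsExposure, nSnpsMediator = nSnpsMediator,
      nMediators = nMediators, mediatorNames = mediatorNames,
      mafRange = mafRange, ldBlockSize = ldBlockSize, ldRho = ldRho,
      ldStructure = ldStructure, h2Exposure = h2Exposure,
      h2Mediator = h2Mediator, betaXM = betaXM, betaMY = betaMY,
      betaMM = betaMM, betaXYdirect = betaXYdirect,
      confounderStrength = confounderStrength,
      ageEffectExposure = ageEffectExposure,
      ageEffectHazard = ageEffectHazard, sexEffectHazard = sexEffectHazard,
      baselineHazard = baselineHazard, followupYears = followupYears,
      gwasNExposureArm = gwasNExposureArm, gwasNOutcomeArm = gwasNOutcomeArm,
      effectDistribution = effectDistribution)
}

## Pearson correlation of two Bernoulli(p) indicators obtained by
## thresholding a bivariate standard normal with latent correlation r.
## The orthant probability is reduced to a one-dimensional integral.
.binaryCorr <- function(r, p) {
  t <- stats::qnorm(p)
  if (abs(r) < 1e-12) return(0)
  p11 <- stats::integrate(function(z) {
    stats::pnorm((t - r * z) / sqrt(1 - r^2)) * stats::dnorm(z)
  }, -Inf, t, rel.tol = 1e-10)$value
  (p11 - p^2) / (p * (1 - p))
}

## Latent correlation producing a target genotype correlation at a given MAF.
.calibrateLatent <- function(target, p) {
  if (target <= 0) return(0)
  stats::uniroot(function(r) .binaryCorr(r, p) - target,
                 lower = target * 0.5, upper = 1 - 1e-9,
                 tol = 1e-9, extendInt = "upX")$root
}

#' Variant panel shared by all simulated samples
#'
#' Draws the variant metadata (positions, alleles, allele frequencies, LD
#' blocks) and the per-variant true trait effects once, so that the cohort
#' and both GWAS arms are sampled from the same generative law. Exposure
#' instruments and each mediator's instruments occupy separate variants;
#' per-allele effects are scaled so each genetic score has the configured
#' variance fraction (accounting for within-block LD). Blocks are placed
#' 20 Mb apart so variants in different blocks are unlinked.
#'
#' When `ldRho > 0`, allele frequency is constant within a block (strongly
#' correlated genotypes with very different frequencies are not attainable).
#'
#' @param config a [SimulationConfig-class].
#' @return a `data.frame` with one row per variant: `variant_id`,
#'   `chromosome`, `base_pair_location`, `effect_allele`, `other_allele`,
#'   `maf`, `block`, `role`, `trueBeta`.
#' @export
simulateVariantPanel <- function(config) {
  validObject(config)
  counts <- c(exposure = config@nSnpsExposure,
              stats::setNames(rep(config@nSnpsMediator, config@nMediators),
                              config@mediatorNames))
  counts <- counts[counts > 0]
  role <- rep(names(counts), counts)
  J <- length(role)
  bs <- config@ldBlockSize
  ## blocks never straddle trait roles
  block <- integer(J)
  off <- 0L
  for (r in names(counts)) {
    idx <- which(role == r)
    block[idx] <- off + ((seq_along(idx) - 1L) %/% bs) + 1L
    off <- max(block[idx])
  }
  nBlocks <- max(block)
  chrom <- ((seq_len(nBlocks) - 1L) %% 22L) + 1L
  tier <- ((seq_len(nBlocks) - 1L) %/% 22L)
  blockStart <- 1e6 + tier * 2e7
  withinIdx <- stats::ave(seq_len(J), block, FUN = seq_along)
  pos <- blockStart[block] + (withinIdx - 1L) * 5000L
  if (config@ldRho > 0) {
    blockMaf <- stats::runif(nBlocks, config@mafRange[1], config@mafRange[2])
    maf <- blockMaf[block]
  } else {
    maf <- stats::runif(J, config@mafRange[1], config@mafRange[2])
  }
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, J, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), character(1))
  panel <- data.frame(
    variant_id = sprintf("rs%05d", seq_len(J)),
    chromosome = as.character(chrom[block]),
    base_pair_location = as.numeric(pos),
    effect_allele = ea, other_allele = unname(oa),
    maf = maf, block = block, role = role,
    trueBeta = 0, stringsAsFactors = FALSE
  )
  ## scale raw effects so each score has its theoretical variance fraction
  for (r in names(counts)) {
    idx <- which(role == r)
    h2 <- if (r == "exposure") config@h2Exposure else config@h2Mediator
    raw <- if (config@effectDistribution == "equal") {
      sample(c(-1, 1), length(idx), replace = TRUE)
    } else {
      stats::rnorm(length(idx))
    }
    v <- 2 * maf[idx] * (1 - maf[idx])
    S <- sum(raw^2 * v)
    if (config@ldRho > 0 && bs > 1) {
      for (b in unique(block[idx])) {
        jj <- which(block[idx] == b)
        if (length(jj) < 2) next
        for (a1 in jj) for (a2 in jj) {
          if (a1 >= a2) next
          rho <- if (config@ldStructure == "ar1")
            config@ldRho^abs(a1 - a2) else config@ldRho
          S <- S + 2 * raw[a1] * raw[a2] * rho *
            sqrt(v[a1] * v[a2])
        }
      }
    }
    panel$trueBeta[idx] <- raw * sqrt(h2 / S)
  }
  panel
}

#' Simulate additively coded genotypes
#'
#' Draws an individuals-by-variants matrix of 0/1/2 genotypes from the
#' variant panel. Each of the two haplotypes per individual is generated
#' from a Gaussian copula: within an LD block, latent normals follow an
#' AR(1) or exchangeable correlation whose parameter is calibrated so the
#' resulting *genotype* correlation of adjacent variants equals `ldRho`;
#' thresholding at the normal quantile of the allele frequency yields
#' Hardy-Weinberg genotype proportions by construction. Blocks (and, with
#' `ldRho = 0`, all variants) are independent.
#'
#' @param config a [SimulationConfig-class].
#' @param n number of individuals (defaults to `nIndividuals`).
#' @param panel variant panel from [simulateVariantPanel()]; drawn fresh
#'   when `NULL`.
#' @return list with `genotypes` (integer matrix, columns named by variant)
#'   and `panel`.
#' @examples
#' cfg <- simulationConfig(nIndividuals = 500, nSnpsExposure = 10,
#'                         nMediators = 0, nSnpsMediator = 0)
#' set.seed(1)
#' g <- simulateGenotypes(cfg, n = 500)
#' dim(g$genotypes)
#' @export
simulateGenotypes <- function(config, n = config@nIndividuals, panel = NULL) {
  validObject(config)
  .stopIfNot(n > 0, "n must be positive")
  if (is.null(panel)) panel <- simulateVariantPanel(config)
  J <- nrow(panel)
  G <- matrix(0L, nrow = n, ncol = J,
              dimnames = list(NULL, panel$variant_id))
  rho <- config@ldRho
  for (b in unique(panel$block)) {
    idx <- which(panel$block == b)
    Jb <- length(idx)
    maf <- panel$maf[idx]
    if (rho == 0 || Jb == 1L) {
      G[, idx] <- matrix(stats::rbinom(n * Jb, 2L, rep(maf, each = n)),
                         nrow = n)
      next
    }
    a <- .calibrateLatent(rho, maf[1])
    t <- stats::qnorm(maf[1])
    g <- matrix(0L, n, Jb)
    for (h in 1:2) {
      Z <- matrix(0, n, Jb)
      if (config@ldStructure == "ar1") {
        Z[, 1] <- stats::rnorm(n)
        s <- sqrt(1 - a^2)
        for (j in 2:Jb) Z[, j] <- a * Z[, j - 1] + s * stats::rnorm(n)
      } else {
        B <- stats::rnorm(n)
        Z <- sqrt(a) * B + sqrt(1 - a) *
          matrix(stats::rnorm(n * Jb), n, Jb)
      }
      g <- g + (Z < t)
    }
    G[, idx] <- g
  }
  list(genotypes = G, panel = panel)
}

#' Pairwise LD table from a genotype matrix
#'
#' Computes r-squared between all variant pairs on the same chromosome
#' within a window, in the three-column layout consumed by
#' [selectInstruments()]. Monomorphic pairs are assigned r2 = 1
#' (conservative: they are never retained together).
#'
#' @param genotypes individuals-by-variants genotype matrix.
#' @param panel variant panel (needs `variant_id`, `chromosome`,
#'   `base_pair_location`).
#' @param windowKb only pairs closer than this many kb are reported.
#' @return `data.frame` with columns `id_a`, `id_b`, `r2`.
#' @export
ldFromGenotypes <- function(genotypes, panel, windowKb = 10000) {
  out <- list()
  for (chr in unique(panel$chromosome)) {
    idx <- which(panel$chromosome == chr)
    if (length(idx) < 2) next
    pos <- panel$base_pair_location[idx]
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq((i + 1), length(idx))) {
        if (abs(pos[i] - pos[j]) >= windowKb * 1000) next
        r <- suppressWarnings(
          stats::cor(genotypes[, idx[i]], genotypes[, idx[j]]))
        out[[length(out) + 1L]] <- data.frame(
          id_a = panel$variant_id[idx[i]],
          id_b = panel$variant_id[idx[j]],
          r2 = if (is.na(r)) 1 else r^2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      r2 = numeric(0)))
  }
  do.call(rbind, out)
}
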