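#' @include utils.R
NULL

.configDefaults <- function() {
  list(
    seed = 1L,
    simulation = list(
      n_individuals = 1e5, n_snps_exposure = 50, n_snps_mediator = 25,
      n_mediators = 1, mediator_names = NULL, maf_range = c(0.05, 0.5),
      ld_block_size = 1, ld_rho = 0, ld_structure = "ar1",
      h2_exposure = 0.1, h2_mediator = 0.1, beta_xm = 0.5, beta_my = 0.4,
      beta_mm = 0, beta_xy_direct = 0.2, confounder_strength = 0.2,
      age_effect_exposure = 0.1, age_effect_hazard = 0.3,
      sex_effect_hazard = log(2), baseline_hazard = 8.46e-4,
      followup_years = 12, gwas_n_exposure_arm = 5e4,
      gwas_n_outcome_arm = 5e4, effect_distribution = "normal"
    ),
    instruments = list(
      p_threshold = 5e-8, r2_threshold = 0.01, window_kb = 10000,
      palindromic_window = 0.08
    ),
    mr = list(
      model = "random", steiger = TRUE, presso = TRUE,
      presso_n_sim = 1000, presso_outlier_alpha = 0.05,
      weak_f_threshold = 10, suppress_weak = TRUE
    ),
    cohort = list(
      covariates = c("age", "sex", "center", "education", "smoking",
                     "alcohol"),
      transform = "zscore"
    ),
    triangulation = list(alpha = 0.05, bonferroni = FALSE),
    output = list(digits = 6)
  )
}

.checkConfigTypes <- function(config) {
  num <- function(x) is.numeric(x) && all(is.finite(x))
  s <- config$simulation
  for (f in c("n_individuals", "n_snps_exposure", "gwas_n_exposure_arm",
              "gwas_n_outcome_arm")) {
    if (!num(s[[f]]) || s[[f]] <= 0) {
      stop(sprintf("config field simulation.%s must be a positive number", f),
           call. = FALSE)
    }
  }
  i <- config$instruments
  for (f in c("p_threshold", "r2_threshold")) {
    if (!num(i[[f]]) || i[[f]] <= 0 || i[[f]] > 1) {
      stop(sprintf("config field instruments.%s must lie in (0, 1]", f),
           call. = FALSE)
    }
  }
  if (!num(i$window_kb) || i$window_kb <= 0) {
    stop("config field instruments.window_kb must be positive", call. = FALSE)
  }
  if (!config$mr$model %in% c("random", "fixed")) {
    stop("config field mr.model must be 'random' or 'fixed'", call. = FALSE)
  }
  a <- config$triangulation$alpha
  if (!num(a) || a <= 0 || a >= 1) {
    stop("config field triangulation.alpha must lie in (0, 1)", call. = FALSE)
  }
  invisible(config)
}

.mergeConfig <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown config field: %s", full), call. = FALSE)
    }
    if (is.null(user[[key]])) next   # explicit nulls keep the default
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      .stopIfNot(is.list(user[[key]]),
                 sprintf("config field %s must be a mapping", full))
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults (significance threshold
#' 5e-8, LD r2 threshold 0.01, window 10,000 kb, triangulation alpha
#' 0.05, ...), rejects unknown keys with a field-level message, and checks
#' field types and ranges. `defaultConfig()` returns the fully defaulted
#' configuration; [writeConfig()] writes a normalized configuration so
#' that write(load(x)) round-trips.
#'
#' @param path YAML file path (`NULL` returns the defaults).
#' @return a validated nested configuration list (class
#'   `trimediate_config`).
#' @export
loadConfig <- function(path = NULL) {
  user <- if (is.null(path)) {
    list()
  } else {
    .stopIfNot(file.exists(path), sprintf("config file not found: %s", path))
    yaml::read_yaml(path)
  }
  config <- .mergeConfig(.configDefaults(), user)
  .checkConfigTypes(config)
  class(config) <- c("trimediate_config", "list")
  config
}

#' @rdname loadConfig
#' @export
defaultConfig <- function() loadConfig(NULL)

#' @rdname loadConfig
#' @param config a configuration list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Build a [SimulationConfig-class] from a pipeline configuration
#'
#' @param config a configuration list from [loadConfig()].
#' @return a [SimulationConfig-class].
#' @export
simulationConfigFromList <- function(config) {
  s <- config$simulation
  K <- s$n_mediators
  simulationConfig(
    seed = config$seed, nIndividuals = s$n_individuals,
    nSnpsExposure = s$n_snps_exposure, nSnpsMediator = s$n_snps_mediator,
    nMediators = K,
    mediatorNames = if (is.null(s$mediator_names)) NULL
                    else as.character(s$mediator_names),
    mafRange = as.numeric(s$maf_range), ldBlockSize = s$ld_block_size,
    ldRho = s$ld_rho, ldStructure = s$ld_structure,
    h2Exposure = s$h2_exposure, h2Mediator = s$h2_mediator,
    betaXM = rep_len(as.numeric(s$beta_xm), K),
    betaMY = rep_len(as.numeric(s$beta_my), K),
    betaMM = s$beta_mm, betaXYdirect = s$beta_xy_direct,
    confounderStrength = s$confounder_strength,
    ageEffectExposure = s$age_effect_exposure,
    ageEffectHazard = s$age_effect_hazard,
    sexEffectHazard = s$sex_effect_hazard,
    baselineHazard = s$baseline_hazard, followupYears = s$followup_years,
    gwasNExposureArm = s$gwas_n_exposure_arm,
    gwasNOutcomeArm = s$gwas_n_outcome_arm,
    effectDistribution = s$effect_distribution)
}
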