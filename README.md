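# trimediate

Triangulated mediation analysis for rare disease outcomes: how much of the
effect of an exposure (body-mass index, in the motivating renal-cancer
application) on a rare time-to-event outcome runs through intermediate
risk factors such as fasting insulin, blood pressure, lipids or
sex-hormone binding globulin?

The package implements the full three-step framework in two parallel,
methodologically independent arms:

1. **Exposure → mediator** — adjusted linear models in a longitudinal
   cohort, and univariable inverse-variance weighted (IVW) Mendelian
   randomization (MR) from GWAS summary statistics.
2. **Mediator → risk** — Cox proportional-hazards models (conditional
   logistic regression for matched nested case-control substudies) in the
   cohort arm; IVW with MR-Egger, MR-PRESSO, Steiger filtering and
   multivariable MR (with conditional F statistics) in the genetic arm,
   after LD clumping (p ≤ 5×10⁻⁸, r² ≤ 0.01 within 10,000 kb) and
   summary-statistic harmonization.
3. **Mediation** — restricted to mediators with directionally concordant,
   significant associations in *both* arms (the triangulation gate), via
   the product method: indirect = a×b with the Sobel standard error

       se(ab) = sqrt(a² se_b² + b² se_a²),

   proportion mediated = indirect/total on the log-risk scale, with
   delta-method intervals.

A synthetic-data generator with a known
exposure → mediator → outcome structure (polygenic instruments, an
unmeasured confounder, exponential survival at ~0.3–1.4% cumulative
incidence, two non-overlapping GWAS arms, matched case-control sets)
makes every stage testable without access-controlled biobank data.

## Worked example

```r
library(trimediate)

cfg <- simulationConfig(nIndividuals = 20000, gwasNExposureArm = 20000,
                        gwasNOutcomeArm = 20000, nSnpsExposure = 25,
                        nSnpsMediator = 15, baselineHazard = 4e-3,
                        confounderStrength = 0)
sim <- simulateStudy(cfg)
sim$groundTruth
#> GroundTruth: total = 0.4000, direct = 0.2000
#>   med1: indirect = 0.2000, proportion mediated = 0.500

mediateCohort(sim$cohort, "med1")
#> MediationResult [cohort arm] mediator 'med1'
#>   total      = 0.4170 (se 0.0293)
#>   indirect   = 0.1918 (Sobel se 0.0152), 95% CI [0.1620, 0.2216]
#>   proportion mediated = 0.460, 95% CI [0.364, 0.555]

mediateMR(sim$sumstats$exposure, sim$sumstats$mediators$med1,
          sim$sumstats$outcome, ld = sim$ld)
#> MediationResult [mr arm] mediator 'med1'
#>   total      = 0.3266 (se 0.0974)
#>   indirect   = 0.2182 (Sobel se 0.0485), 95% CI [0.1232, 0.3132]
#>   proportion mediated = 0.668, 95% CI [0.181, 1.155]
```

Both arms recover the planted total effect (0.40 per SD, hazard ratio
~1.5) and bracket the true proportion mediated of 0.50 — note the much
wider MR interval, a faithful feature of summary-statistic mediation.
`runPipeline(defaultConfig())` executes all three steps end to end,
writes tab-delimited a-path / risk / triangulation / mediation / edge
tables plus a JSON summary and a reproducibility manifest, and returns
the result bundle; `loadConfig()` reads a YAML configuration with
validated fields and filled defaults.

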