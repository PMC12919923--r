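---
title: "Triangulated mediation: models, assumptions and design choices"
author: "trimediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulated mediation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimediate)
```

## The scientific problem

Excess adiposity raises the risk of several cancers, renal cell carcinoma
prominently among them, but the intermediate biology is unclear: does the
effect run through insulin, blood pressure, lipids, sex-hormone binding
globulin, or something else? `trimediate` implements a three-step framework
for that question:

1. estimate the effect of the exposure (a BMI-like trait, per standard
   deviation) on each candidate mediator;
2. estimate each mediator's association with the rare time-to-event
   outcome;
3. for mediators supported in *both* of two methodologically independent
   arms, decompose the exposure effect into direct and indirect components
   and report the proportion mediated.

The two arms are (i) direct assessment in a longitudinal cohort
(linear models for step 1; Cox proportional-hazards models for step 2,
with conditional logistic regression for mediators measured in a nested
case-control substudy) and (ii) genetically proxied assessment by
two-sample Mendelian randomization (MR) from GWAS summary statistics.
The arms have non-overlapping weaknesses — the cohort arm is vulnerable to
classical confounding and reverse causation, the MR arm to pleiotropy and
weak instruments — so requiring directionally concordant, significant
evidence in both (the *triangulation gate*) is a deliberately conservative
screen. Mediation is only computed for mediators that pass it; that
restriction is enforced structurally by `runPipeline()`.

## The estimators

**MR arm.** With harmonized per-variant effects
$(\hat\beta_{Xj}, \hat\beta_{Yj})$ and outcome standard errors
$\sigma_{Yj}$, the IVW estimate is the precision-weighted average of Wald
ratios $\hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order weights
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, identical to weighted least
squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin.
Heterogeneity is summarized by Cochran's $Q$; the default standard error
is the multiplicative random-effects one, the fixed-effect standard error
inflated by $\max(1, \sqrt{Q/(J-1)})$. The random-effects model is the
field's default for polygenic instrument sets and never reports *less*
uncertainty than the fixed model; both are available.

Sensitivity machinery follows standard practice: MR-Egger (weighted
regression *with* intercept after orienting exposure effects positive;
the intercept tests unbalanced pleiotropy), MR-PRESSO (a parametric
simulation of the leave-one-out residual sum of squares giving a global
test and per-variant outlier p-values, Bonferroni-thresholded), and
Steiger filtering (variants explaining more variance in the outcome than
in the exposure, by the $t^2/(t^2+n-2)$ approximation, are presumed
reverse-causal and dropped). The pipeline applies Steiger before
MR-PRESSO before estimation; the order is a convention, configurable, and
recorded in the dropped-variant reason codes. For a binary outcome the
Steiger variance explained uses the observation-scale approximation from
beta, standard error and sample size; a liability-scale version would
shift both sides similarly and was not implemented.

The mediation b-path in the MR arm comes from multivariable MR: weighted
regression without intercept of outcome betas on the mediator *and*
exposure beta columns, giving the mediator effect conditional on the
exposure. Instrument strength for that coefficient is the conditional F
(weighted residual $Q$ of the mediator's betas regressed on the other
exposures', divided by $J-K+1$, in the Sanderson–Windmeijer spirit,
treating the other exposures' betas as fixed); below 10 the estimate is
flagged and, by default, the mediation quantities are reported as not
calculated rather than as numbers nobody should trust.

**Cohort arm.** Mediators are transformed to match the scale of the GWAS
used in the genetic arm (z-score by default; natural log and Blom
inverse-normal-rank transforms are provided, the latter with offset
$c = 3/8$ and average ranks for ties). The a-path is a linear model of
the transformed mediator on the per-SD exposure; the b-path a Cox model
of the mediator additionally adjusted for the exposure; the total effect
a Cox model of the exposure — all with the configured adjustment set
(age, sex, center, education, smoking, alcohol by default), follow-up
time as the timescale, and Efron tie handling (more accurate than
Breslow at no interface cost). Values below a limit of detection are
imputed as LOD$/\sqrt 2$. For matched nested case-control data the
log-odds come from conditional logistic regression on the matched sets;
with 1:1 binary-exposure pairs this reduces exactly to the
discordant-pair ratio, which the tests exploit as a closed-form oracle.

**Mediation.** The indirect effect is the product $a \times b$ with the
Sobel standard error $\sqrt{a^2\sigma_b^2 + b^2\sigma_a^2}$, which
assumes independently estimated paths — exact for two-sample MR, an
approximation in the cohort arm where one sample supplies both paths (a
Monte-Carlo interval from the two sampling distributions is offered as a
cross-check). The proportion mediated is indirect/total on the log-risk
scale — never on the risk-difference scale, since the source estimates are
hazard and odds ratios — with a first-order delta-method interval
treating the two inputs as independent. Values outside $[0, 1]$ are
reported verbatim with a flag, never truncated. The direct effect is
reported both ways (total − indirect, and the exposure coefficient
adjusted for the mediator); the product-method indirect is primary, and
any discrepancy between the two direct versions is visible in the output
rather than hidden.

Because both paths use the *same* mediator scale, the indirect effect and
the proportion mediated are invariant to how the mediator is scaled; the
a and b coefficients individually are not, which is why the
transformation is recorded on every estimate.

## Instrument selection and harmonization

Instruments are genome-wide significant variants ($p \le 5\times10^{-8}$)
pruned by greedy LD clumping: sort by p (ties broken by chromosome,
position, identifier — determinism matters more than any particular tie
rule), accept the best remaining variant, discard same-chromosome
variants within 10,000 kb with $r^2 > 0.01$, repeat. Missing LD for a
pair inside the window is treated as $r^2 = 1$: a possibly-correlated
pair is never retained. Pairs beyond the window are retained whatever
their LD — the window defines the rule's reach. Variants are matched
across studies by identifier only; a chromosome:position fallback would
help with real data from mixed panels and is a documented limitation.

Harmonization aligns outcome records to the exposure's effect allele,
flipping the outcome beta and complementing its allele frequency when the
alleles are swapped. Palindromic variants (A/T, C/G) are kept only when
both allele frequencies are outside 0.42–0.58 (window 0.08, a common
field convention; configurable) *and* fall on the same side of 0.5 —
otherwise strand cannot be resolved and the variant is dropped with a
reason code. Every removal, here and in the sensitivity filters, carries
a machine-readable reason (`missing_in_outcome`, `allele_mismatch`,
`palindromic_ambiguous`, `presso_outlier`, `steiger_reverse`), so the
filter counts in the run logs always reconcile.

## The synthetic-data generator

Real data of this kind (a half-million-person biobank, a matched
case-control substudy, a consortium case-control GWAS) are
access-controlled, so the package carries a generator whose defaults are
the study conditions everything else is tested under:

* a cohort of 100,000 followed 12 years with a constant-hazard
  (exponential) outcome calibrated to ~1,400 events — the same event
  yield, at a fifth the person-years, as the motivating cohort; the
  exponential choice makes the log hazard ratio available in closed form;
* 50 exposure instruments and 25 per mediator, independent by default
  (the post-clumping regime the estimators assume), jointly explaining
  10% of trait variance; optional LD blocks via a Gaussian copula per
  haplotype whose latent correlation is calibrated numerically so the
  *genotype* correlation of adjacent variants equals `ldRho` (AR(1) or
  exchangeable), with Hardy–Weinberg proportions by construction;
  per-variant effect sizes are N(0, 1)-distributed before scaling (a
  realistic spread of instrument strengths, under which some variants
  miss genome-wide significance) or, with
  `effectDistribution = "equal"`, equal in magnitude so that the full
  panel behaves as genuine instruments — the setting the recovery
  simulations use so that "50 instruments" means 50;
* structural effects `betaXM = 0.5`, `betaMY = 0.4`,
  `betaXYdirect = 0.2`: total log-hazard 0.4 per SD (hazard ratio ~1.5,
  the order of magnitude of the adiposity–renal-cancer association) and
  proportion mediated 0.5;
* a latent standard-normal confounder loading on exposure, mediators and
  hazard (`confounderStrength = 0.2` by default) — unmeasured by design,
  so the cohort arm is demonstrably confoundable while the genetic arm,
  whose instruments are independent of the confounder, is not;
* measured covariates: age loads weakly on the exposure and more strongly
  on the hazard, sex doubles the hazard (the well-known male excess in
  renal cancer); center, education, smoking and alcohol are generated as
  adjustment-set decoration with no hazard loading;
* two GWAS arms of 50,000 drawn from non-overlapping individuals (the
  two-sample assumption holds exactly), sharing one variant panel and one
  set of true per-allele effects; the outcome arm is analysed as a
  case-control GWAS of the end-of-follow-up event indicator by exact
  per-variant logistic regression (fitted for all variants at once by a
  batched Newton iteration that reproduces `glm` to numerical precision);
* a nested case-control builder with incidence-density sampling: controls
  are drawn, without replacement, from participants still at risk at the
  case's event time, matched exactly on sex and within tolerance on age.
  The timescale of control selection in the motivating substudy is not
  published; incidence-density sampling is assumed, and a participant
  sampled as a control may later be a case in their own set.

What the generator deliberately does *not* emulate: realistic LD maps,
population stratification, assortative mating, sex-specific genetic
architecture, time-varying exposures, competing risks, or measurement
error/regression dilution. Passing tests therefore demonstrate that the
estimators recover what they claim *under their own assumptions*; they do
not certify behaviour on real biobank data, where those unmodelled
features are exactly what bites.

## Numerical choices and degenerate inputs

* P-values are two-sided normal throughout the summary-statistic code,
  matching large-sample practice; cohort models report their own Wald
  p-values on the same convention.
* Weighted fits go through a QR decomposition; a rank-deficient design is
  an error, except that an all-zero exposure column in multivariable MR
  is excluded with an `NA` estimate (so a one-informative-column fit
  reduces exactly to univariable IVW, a tested identity).
* A single-variant IVW degrades to the Wald ratio with a warning; an
  empty instrument set is a classed warning (`trimediate_empty_instruments`),
  distinct from an error, so callers can branch on it.
* MR-PRESSO requires a seed (its outlier list must be reproducible) and
  at least 100 simulations; p-values use the add-one convention
  $(1 + \#\{T^* \ge T\})/(n_{\mathrm{sim}}+1)$.
* Steiger ties (equal variance explained on both sides) are retained —
  only a strictly greater outcome-side $r^2$ is evidence of reversal.
* The event-time generator solves for the baseline hazard by
  one-dimensional root finding, either against the realized linear
  predictor (exact) or its theoretical normal approximation; the default
  8.46e-4/year was fixed this way against the 1,400-event target.
* Matching with a zero tolerance on a continuous variable yields zero
  pairs and a warning, not an error; unmatched cases are reported.

## Problem sizes used by the test suite

The validation suite re-derives every oracle it asserts against
(weighted-lm fits, explicit normal equations, brute-force clumping scans,
Monte-Carlo product/ratio distributions) and runs parameter-recovery
simulations at the following sizes, chosen to exercise the study
conditions at desk scale: MR recovery at 200 replicates of two 50,000
arms with 50 instruments (true OR 1.44 per SD); cohort recovery at 200
replicates of 100,000 with ~1,400 events (true HR 1.33 per SD); mediation
recovery at 100 replicates per arm (truths 0.50 cohort / 0.25 MR, the MR
world using a 5%-case outcome arm, the case fraction of the motivating
consortium GWAS); Sobel coverage at 2,000 replicates; MR-PRESSO type-I
error at 500 null replicates; Steiger discrimination at 200 replicates of
20 forward + 5 reverse variants; and the triangulation gate at 4,000
null draws plus component-level simulated worlds. Under independent null
arms with two-sided tests, the expected eligibility rate of the gate is
$\alpha^2/2$ (both arms significant, $\alpha^2$; signs agreeing given
that, $1/2$), which is what the suite asserts.

## Known limitations

The cohort arm reuses one sample for both mediation paths, so the Sobel
independence assumption is approximate there. The conditional-F
computation conditions on the other exposures' estimated betas rather
than propagating their uncertainty. Identifier-only variant matching and
the absence of proxy-variant lookup limit direct use on heterogeneous
real summary statistics. The concordance gate's significance level
defaults to 0.05 per mediator without multiple-testing correction
(a Bonferroni option exists but is off by default, matching the framing
of the analysis as a screen rather than a confirmatory family); and the
proportion mediated is a ratio of noisy estimates whose point value
should never be read without its interval — the pipeline always reports
both.
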