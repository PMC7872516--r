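---
title: "Lifestyle, the lipidome, and CHD: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifestyle, the lipidome, and CHD: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmed)
```

`lipidmed` estimates how much of the protective association between combined
healthy-lifestyle factors (HLFs) and coronary heart disease (CHD) is carried
by an NMR-style lipoprotein lipid profile, in a nested case–control design.
This vignette documents the statistical models, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical and design decisions a maintainer should know about.

## Lifestyle scoring

Five binary factors are derived from raw fields: never smoking; moderate
alcohol use (weekly-but-not-daily drinking, or daily drinking of **less
than** 30 g pure alcohol — the 30 g boundary itself counts as heavy use);
healthy diet (at least 4 of 6 food-frequency components); physical activity
at or **at/above** the sex-specific median of MET-hours/day (the median is
computed in whatever cohort is passed in, configurable via
`activity_thresholds`); and healthy adiposity (BMI in the closed interval
[18.5, 27.9] kg/m² **and** waist circumference strictly below 90 cm in men /
85 cm in women). Boundary conventions are taken literally from the factor
definitions. Two pre-specified sensitivity variants are provided: dropping
the alcohol factor (count over four factors) and a strict adiposity rule
(BMI ≤ 24.9, WC < 90/80). Missing raw fields are hard errors naming the
field and participant — there is no imputation rule to substitute.

Because "physically active" is defined against the realized sex-specific
median, its prevalence is structurally ~50%; the generator honors a
configured activity prevalence only at 0.5.

## Metabolite preparation

Each lipid measure is mapped to normal quantiles by the rank-based
inverse-normal transform with the Blom offset 3/8 (the most common
epidemiological convention; any fixed offset preserves ranks). Ties get the
average fractional rank, so duplicated concentrations map to equal values.
By default the quantile scores are then centered and rescaled to sample mean
exactly 0 and SD exactly 1: raw Blom scores have SD visibly below 1 in
finite samples (0.905 at n = 5), and downstream effect sizes are reported
"per SD", so the exact-unit-SD convention is the one the estimates assume.
`standardize = FALSE` returns the raw quantiles. Transformation is computed
on the pooled analysis sample (cases and controls together); association
models adjust for case/control status, and pooling is configurable by
passing subsets.

Duplicate-measurement quality control summarises per-pair CVs (SD/mean of
the two replicates), averaged per marker, as a median and IQR across
markers. Principal components of the transformed panel (default `k = 5`,
with a warning if they explain less than 95% of total variance) feed the
joint mediation analysis.

## Association layers

HLF → metabolite associations are ordinary least squares of the transformed
marker on either the three-level HLF group (reference "0–1") or the
continuous count, adjusted for age, sex, fasting time (< 8 vs ≥ 8 h; fasting
is recorded in hours and dichotomized at 8), 10 study areas (9 indicator
columns), 3-level education (2 indicators) and case/control status.
Metabolite → CHD associations are maximum-likelihood logistic regressions
per 1-SD of the marker in CHD cases and controls only, with smoking status
replacing case/control status in the adjustment set. Wald 95% CIs
(estimate ± 1.96 SE) are used throughout. Multiplicity across the marker
panel is controlled with Benjamini–Hochberg adjusted p-values at FDR < 0.05.
Effect-modification tests are likelihood-ratio tests comparing models with
and without the cross-product term.

## Mediation

For each marker, a linear mediator model is fit **in controls only** and a
logistic outcome model in CHD cases plus controls, both adjusted for age,
sex, fasting time, study area and education. With exposure contrast `a` vs
`a*` (default: one additional HLF above the control-sample mean; both
configurable), the rare-outcome closed forms give

$$\mathrm{NIE} = (\theta_2\beta_1 + \theta_3\beta_1 a)(a-a^*), \qquad
\mathrm{NDE} = \big[\theta_1 + \theta_3(\beta_0 + \beta_1 a^* + \beta_2'c +
\theta_2\sigma^2)\big](a-a^*) + \tfrac12\theta_3^2\sigma^2(a^2-a^{*2}),$$

with TE = NDE + NIE by construction and the proportion mediated NIE/TE on
the log-odds scale. The covariate reference vector `c` defaults to the
control-sample means of the mediator-model design columns (for factors,
their sample proportions); with no interaction term `c` does not enter the
estimands at all. The rare-outcome (OR ≈ RR) approximation is assumed
throughout; the generator's default marginal CHD risk is 2% so it holds
comfortably, and the ground-truth integrator warns above 5%.

**Interaction policy.** `mediate(interaction = "auto")` screens each marker
with the exposure-by-mediator LRT and reports the no-interaction
decomposition when the product term is not significant at 0.05 (the
interaction-allowing fit is used otherwise); `"on"`/`"off"` force either
model.

**Uncertainty.** Standard errors are delta-method: the gradient of each
estimand with respect to the stacked parameter vector (mediator
coefficients, residual variance, outcome coefficients), with the covariance
block-diagonal across the two fits — the standard parametric-mediation
treatment; a nonparametric bootstrap is the cross-check and agrees within
15% at n = 2000 in the test suite. The sampling variability of the residual
variance (2σ⁴/(n−p)) is included by default
(`delta_method_ci(include_sigma2_var = FALSE)` drops it). Gradients for the
natural effects are analytic (verified against central finite differences to
1e-6); the four-way components use numerical gradients.

**Four-way decomposition.** The total excess relative risk is split into
controlled direct effect, reference interaction, mediated interaction and
pure indirect effect. Two scales are reported, because they answer different
questions and satisfy different identities:

- *Excess-RR scale* (`$err`): the counterfactual definitions are integrated
  exactly under the rare-outcome risk model using Gaussian
  moment-generating-function identities, so the four components sum to
  `exp(TE) − 1` to machine precision and agree with Monte-Carlo
  counterfactual integration. On this additive scale a purely multiplicative
  model still has non-zero interaction components even when θ₃ = 0 — they
  are second-order products such as `(e^{θ₁Δ}−1)(e^{θ₂β₁Δ}−1)` — which is a
  property of the scale, not an artifact.
- *Multiplicative (log-OR) scale* (`$log`): `cde = (θ₁+θ₃m*)(a−a*)`,
  `int_ref = NDE − cde`, `int_med = θ₃β₁(a−a*)²`,
  `pie = (θ₂+θ₃a*)β₁(a−a*)`. These sum to TE exactly and the interaction
  parts vanish identically when no product term is fitted, matching the
  intuition that "no θ₃, no interaction".

The reference mediator level `m*` defaults to the model-implied mediator
mean at `a*` and `c`; it is a free choice and is configurable.

**Joint mediation.** The top principal components are treated as multiple
mediators: one mediator model per component in controls, a single outcome
model containing all components (no interactions), joint
NIE = Σₖ θ₂ₖβ₁ₖ(a−a*), joint pm = NIE/TE, with the delta method over all
stacked fits. A multi-mediator outcome model (rather than summing univariate
NIEs) is the default because the components are orthogonal by construction
and the multi-mediator model keeps the direct effect interpretable; summing
univariate fits differs under the logit's non-collapsibility.

**Dichotomization experiment.** `dichotomization_bias_experiment()` runs the
simulation behind the caveat that dichotomizing a continuous exposure can
bias mediation estimates: it compares the proportion mediated estimated with
a continuous standard-normal exposure vs the same exposure split at its
median, over a grid of exposure–mediator effect sizes. Bias grows with the
exposure–mediator association and is negligible when that association is
weak.

## Genetic scores

Within a gene window, variants are selected iteratively: test each remaining
candidate's association with LDL-C conditional on age, sex, 10 ancestry PCs
and the previously selected variants; pick the smallest p-value (ties broken
by smallest genomic position — the procedure is otherwise order-invariant);
stop when the best conditional p ≥ 0.05; prune remaining candidates with
r² > 0.3 to the pick; repeat. The first iteration therefore reads
"select the top variant, prune its LD partners, then go conditional", which
follows the procedure's natural sentence order. Monomorphic variants are
excluded up front. The inner loop uses Frisch–Waugh residualization (exact
equivalence to the joint-model t-test, verified in tests); final weights
come from one joint linear model containing all selected variants.

Weights are stored as positive magnitudes with each variant oriented to its
LDL-C-**lowering** (exposure) allele, so a higher score means more
pharmacologically protective alleles and associates with *lower* LDL/IDL
measures; consequently "higher genetic risk" in the joint four-group and
stratified analyses is a score **below** the median. Score–metabolite
associations are reported per 2 SD of the inverse-normal transformed score,
adjusted for age, sex, study area and 10 genotype PCs. The selection cohort
(default 13,060) is disjoint from the analysis cohort by construction.
External (re-weighted) score definitions round-trip through JSON.

## The synthetic study generator

The generator emulates the statistical structure the analysis assumes, with
known ground truth:

- **Design**: a 60,000-person source cohort (ages 30–79), 927 CHD + 1114
  ischemic-stroke + 1127 intracerebral-hemorrhage cases and 1513 common
  controls frequency-matched to combined cases by 5-year age bin, sex and
  10 study areas (largest-remainder allocation; matching is by frequency,
  not 1:1 pairing). Eligibility excludes prevalent CVD/cancer and statin
  use. Stroke cases are generated and carried but no stroke models are fit.
- **Lifestyle**: five factors from a Gaussian copula (pairwise latent
  correlation 0.15) with age/sex/education effects on each latent
  propensity; prevalences (0.58, 0.10, 0.45, 0.50, 0.70) chosen so the mean
  HLF count ≈ 2.3, the scale of a middle-aged Chinese cohort; raw fields are
  constructed so that `classify_hlf()` reproduces the intended flags, and
  the stored flags *are* the classifier's output.
- **Lipidome**: 61 markers on three latent axes (VLDL/TG, LDL/ApoB, HDL)
  with within-class loadings ≈ 0.98 — lipoprotein measures are near-sums of
  each other, so the panel is deliberately near-collinear and the top 5 PCs
  carry ≥ 95% of variance; per-HLF effects give a 4–5 vs 0–1 contrast of
  about −0.5 SD on the VLDL axis and +0.35 SD for large HDL, the scale of
  the strongest reported lifestyle–lipidome differences.
- **Genotypes**: latent multivariate-Gaussian haplotypes thresholded at the
  allele frequency (two haplotypes ⇒ Hardy–Weinberg), within-block
  correlation `ld_decay^|i−j|`, independence across blocks; causal variants
  shift LDL-C (mmol/l per allele) and the LDL/ApoB-related markers.
- **Outcome**: logistic CHD with a direct per-HLF effect (−0.20) and sparse
  per-SD metabolite effects (0.22 small VLDL particles, 0.24 ApoB/ApoA1,
  −0.15 large HDL); the intercept is calibrated at run time to a 2% marginal
  risk so the rare-outcome approximation underlying the mediation formulas
  holds.
- **QC duplicates**: 137 participants measured twice with multiplicative
  noise; the noise SD is the configured CV statistic divided by √(2/π)
  (two-replicate CVs are half-normal), with lognormal per-marker precision
  multipliers so the across-marker IQR is realistic.
- **Determinism**: one seed expands into fixed per-stage substreams, so
  stages can be regenerated in isolation and runs are byte-reproducible.

**Ground truth.** Because every metabolite enters the outcome linearly with
Gaussian noise whose covariance does not depend on exposure, the
cross-world means cancel and the per-marker true NIE on the log-RR scale is
exactly `θ₂ⱼ bⱼ (a−a*)`, where `bⱼ` is the covariate-partialled slope of the
marker's lifestyle signal on the HLF count — equal to the shared per-factor
effect under the default homogeneous effect matrices, and computed by
numerical integration of the copula lifestyle layer (a large Monte-Carlo
draw of flag configurations) otherwise. The true total effect is
`(θ_direct + Σⱼ θ₂ⱼ bⱼ)(a−a*)`, so TE = NDE + NIE holds identically in the
truth object. With heterogeneous per-factor effects the count is not a
sufficient statistic for the flags and the truth is the best linear
approximation; the defaults keep effects homogeneous so it is exact.

**What passing tests do and do not show.** The generator has Gaussian
factor structure, logistic outcomes, no measurement error in covariates, no
missing data, exact model specification, and lifestyle effects that are
linear in the flag count. Parameter recovery on it demonstrates that the
estimators are correct *under the assumed models*; it cannot demonstrate
robustness to model misspecification, residual confounding, or selection
effects beyond frequency matching. Single-mediator estimates on the
correlated default panel absorb signal from correlated causal markers
(mediator–mediator confounding), exactly as correlated lipid measures do in
real data — recovery tests therefore use single-marker configurations where
the single-mediator assumptions hold.

## Numerical choices and degenerate inputs

- Logistic fits flag non-convergence and fitted probabilities within 1e-10
  of 0/1 (separation) as errors with diagnostics; rank-deficient designs
  fail listing the aliased columns.
- The inverse-normal transform refuses constant columns and n < 3; the PCA
  step refuses k beyond the matrix rank; duplicate pairs with mean zero are
  excluded with a warning.
- `proportion_mediated` is undefined at TE = 0 (flagged), and flagged
  "inconsistent" when NDE and NIE have opposite signs.
- Exhausted control strata are errors naming the stratum under
  `strict = TRUE` (the default for direct calls); the generator samples with
  `strict = FALSE`, capping at stratum capacity and redistributing the
  shortfall with a message, since sparse oldest-age strata can empty at
  small simulation scales.
- Equal selection p-values (exactly tied) are broken by genomic position;
  p-values are continuous so this is a measure-zero tie-break.
- Monte-Carlo counterfactual integration shares the normal draws across
  exposure worlds; with no interaction the log-ratio is then exact
  (zero Monte-Carlo variance), and tolerance checks add a 1e-9 floor.

## Problem sizes used in the checks

The test suite exercises the stated study conditions directly: recovery of
the proportion mediated uses 200 nested case–control replicates per
scenario (≈ 2400 analysed participants each, true pm 0/0.10/0.25), oracle
agreement uses ten fixtures at 10⁶ Monte-Carlo draws, the bootstrap
comparison 500 resamples at n = 2000, variant-selection recovery 50 seeds
with 50 variants at n = 13,060, and null calibration 500 interaction-test
simulations plus 400 null 61-marker panels. The acceptance script repeats
the same computations at moderately smaller replicate counts and prints
every quantity it reports.

## Known limitations

- The mediation estimands rely on the rare-outcome approximation and on the
  usual no-unmeasured-confounding assumptions; no sensitivity analysis for
  mediator–outcome confounding is provided.
- Correlated markers cannot be disentangled by single-mediator analysis;
  the joint-PC estimate is the supported summary of the panel's combined
  mediation.
- The generator matches marginal structure (prevalences, factor axes, LD
  blocks, risks), not any real cohort's joint distribution; no survival
  times are generated (case status only).
- No weighted HLF score is provided — the unweighted count is deliberately
  the exposure.
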