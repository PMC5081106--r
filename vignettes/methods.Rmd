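---
title: "Estimating diabetes prevalence trends from heterogeneous surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diabetes prevalence trends from heterogeneous surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

National time series of adult diabetes prevalence have to be assembled from
population-based health-examination surveys that differ in almost every
respect that matters: the biomarker and cutoff used to define diabetes
(fasting plasma glucose at 7.0 mmol/L or another threshold, 2-hour OGTT,
HbA1c, or only a population mean glucose), the representativeness of the
sample (national, subnational, community), rural/urban selectivity, the age
bands reported, and sample size. Most country-years have no survey at all.
`diabtrends` implements the full estimation chain for this situation:

1. **Cross-walk** observations made under alternative diabetes definitions
   to a single primary outcome — fasting plasma glucose ≥ 7.0 mmol/L, or a
   diagnosis history, or use of glucose-lowering medication — propagating
   the conversion uncertainty.
2. **Fit** a Bayesian hierarchical probit model that pools all harmonised
   datapoints across countries, years, ages and study types.
3. **Derive** the quantities of public-health interest: age-standardised
   and crude prevalence, counts of adults with diabetes, a demographic
   decomposition of count changes, and the probability of meeting the
   global target of halting the rise in age-standardised prevalence by
   2025 at its 2010 level.
4. **Validate** by withholding data, refitting, and scoring.

Because the survey microdata that motivate this design are confidential,
the package ships a **synthetic-world generator** that draws ground-truth
prevalence surfaces from the same structural assumptions the model makes,
simulates surveys with realistic error structure, and therefore lets every
stage be tested against a known answer.

## The synthetic world

A world consists of a three-level geographic hierarchy (countries within
regions within super-regions), years (default 1980–2014), one or both
sexes, and the fixed adult age grid 18–19, 20–24, …, 75–79, 80+ (intervals
half-open; the open top group is given midpoint 82.5). On the probit scale
the true prevalence at the reference age (50 years) follows

μ(c, t) = β₀ + β₁ t̃ + u(s) + v(r) + w(c) + (slope deviations)·t̃ +
wiggle(t) + Z(c, t) λ,

with independent normal level and slope deviations at each hierarchy
level, a smooth non-linear "wiggle" (a natural-spline function of year,
orthogonalised against the linear trend) at the global and country level,
and linear effects of four z-scored covariates (mean years of education,
urban population fraction, a food-availability score, mean BMI). Covariate
series have country-specific trends plus smooth AR(1) fluctuations, so no
covariate is an exact linear function of time. The age profile is a
concave-in-age curve f(a) (zero at age 50) multiplied by
exp(γ·(μ − β₀)), so the rise of prevalence with age is steeper wherever
prevalence is higher. Prevalence is the probit inverse of μ + steepened
f(a).

Default generator values were chosen once, as plausible study conditions:
intercept −1.6 (≈ 5.5% at age 50 mid-period), global trend +0.11 probit per
decade (the scale of the observed global rise over 1980–2014), hierarchy
SDs 0.10–0.15 (levels) and 0.04–0.05 (slopes per decade), age slope 0.03
per year with curvature −2·10⁻⁴, steepness γ = 0.25, rural–urban gap 0.15
probit, community-study offset +0.2 probit, subnational offset +0.05,
study-level non-sampling SDs 0 / 0.06 / 0.12 probit for national /
subnational / community scopes. The steep-trend and flat-trend checks used
by the test suite program slopes of +0.35 and 0 respectively. None of
these values is an estimate of the corresponding real-world quantity; they
define reproducible test conditions.

Surveys are simulated per study: the stratum's true prevalence is the
population-weighted mean of the covered age groups (on the urban or rural
sub-surface for urban-only/rural-only studies, shifted ±gap·urbanisation
share); the scope offset and a study-level non-sampling error are added on
the probit scale; and the observed count is binomial. Alternative
definitions shift the probit by a definition offset (2hOGTT +0.2,
HbA1c +0.1, non-standard FPG cutoffs −0.45 per mmol/L above 7.0);
mean-FPG sources report the mean implied by the linear map
probit(prevalence) = −7.5 + 1.1·(mean FPG), observed with standard error
1.2/√n. Every study consumes a random substream derived from
(seed, study index), so simulation output is reproducible and independent
of iteration order. Observed proportions of exactly 0 or 1 are
continuity-corrected to (x + 0.5)/(n + 1) before any probit transform;
interior proportions are untouched.

What the generator deliberately does **not** emulate: non-sampling error
that is correlated within countries over time, measurement-device drift,
age-misreporting, survey non-response, or covariates measured with error.
Passing recovery tests therefore demonstrate that the machinery is
internally correct and well-calibrated under its own assumptions — not
that real-world estimates carry the same accuracy.

## The cross-walk regressions

Paired observations — strata in which both the primary outcome and one
alternative definition were computed from the same individuals — train,
per source definition, the regression

probit(p_primary) = α + β·probit(p_source) + (age, sex, year, income
terms) + ε.

Datapoints based on fewer than 25 people are excluded before fitting or
applying any conversion. Candidate interactions of the source term with
age, sex and year are enumerated exhaustively (8 models) and the subset
minimising BIC is kept; with more than 400 training datapoints the
regression also carries regional random intercepts (fitted by maximum
likelihood so BIC comparisons remain valid). Sources reporting only a mean
fasting glucose use the simplest monotone map, a two-parameter linear
regression of the primary probit on the mean.

Both regression sides are taken on the probit scale: conversion
regressions of this kind are often specified directly between prevalences
without a fixed scale, but probit keeps predictions inside [0, 1] and
matches the main model's link, so it is the choice made here. "Income" enters as a stand-in column
(the synthetic worlds supply mean education years); any monotone
income-like covariate can be substituted.

Applying a cross-walk replaces the prevalence by the regression's point
prediction mapped back through the normal CDF, and inflates the standard
error by the delta method on the probit scale: input sampling variance
propagated through the (interaction-adjusted) source slope, plus
coefficient uncertainty x'Vx, plus residual variance and, when present,
the regional random-intercept variance (a new region is assumed). The
reported uncertainty is floored at the input sampling error. Conversion
uncertainty then enters the main model through the datapoint's enlarged
standard error; a hierarchical measurement model would be an alternative,
but the enlarged-SE route keeps the likelihood simple and is conservative.

## The hierarchical probit trend model

Each sex is fitted separately. For datapoint i (country c, year t, age
band B, study s):

probit(p̂ᵢ) ~ Normal(θᵢ, vᵢ + κ²_scope),

θᵢ = μ(c, t) + f̄(B)·exp(γ(μ(c, t) − m₀)) + δ_sub·[subnational] +
δ_com·[community] + (δ_urb·[urban-only] + δ_rur·[rural-only])·(study urban
fraction − country urbanisation) + e_s,

where vᵢ is the delta-method sampling variance of the probit-transformed
stratum prevalence, κ_scope a fitted non-sampling SD per scope, f̄(B) the
mean of the age-spline basis over the band's group midpoints, and e_s a
study random effect with scope-specific variance (national studies are
pinned at zero, implementing the greater influence of national data).

The level surface is

μ(c, t) = a₀(c) + a₁(c)·t̃ + g_world(t) + g_super(t) + g_region(t) +
g_country(t) + Z(c, t)λ,

with year centred at the range midpoint and measured in decades
(decorrelating intercepts and slopes). Country intercepts and slopes are
hierarchically centred — a(c) ~ N(a(region), σ²_country),
a(region) ~ N(a(super-region), σ²_region),
a(super-region) ~ N(global, σ²_super) — which both encodes the intended
borrowing of strength (a data-free country shrinks to its regional level
and trend) and gives the sampler a well-conditioned parameterisation.

Non-linear year components g(·) are second-order random walks per
hierarchy level, carried on a 5-year knot grid and linearly interpolated
to years. They are parameterised non-centrally (innovations are standard
normals scaled by a level-specific SD), start at (0, 0), and have their
remaining level-and-slope component projected out, since those directions
belong to the intercept and trend terms. The age pattern is a natural
cubic spline over the group midpoints with interior knots at ages 35, 50
and 65, zeroed at age 50, multiplied by exp(γ(μ − m₀)) with γ ≥ 0 — a
minimal one-parameter implementation of "steeper age gradients where
prevalence is higher". The exact functional form of this coupling is a
genuinely open design choice; this version is the package's documented
stand-in, and both the knots and γ's prior are configurable.

Covariates are z-scored and then projected orthogonally to every
country's linear time trend. The projected-out components are linear
functions of time within country and are absorbed exactly by the free
country intercepts and slopes, so the span of fitted surfaces is
unchanged; the projection's purpose is identification — without it the
covariate coefficients ride an extreme posterior ridge against the country
intercepts and mix arbitrarily slowly. The practical consequence is that
covariate effects are estimated from within-country non-trend variation
only, and a data-free country is predicted by its hierarchy rather than by
its covariate levels.

Priors: half-normal on every SD (scales 0.3 for levels, 0.15 for slopes,
0.1 for random-walk innovations, 0.3 for study effects, 0.15 for
non-sampling SDs — all configurable), Normal(0, 0.5²) on scope effects,
Normal(0, 0.25²) on covariate effects, half-normal(0.5) on γ, diffuse
normals on the global intercept and trend.

Sampling uses JAGS with at least two chains. The full schedule keeps 5000
post-burn-in draws; the reduced preset keeps 1000 (2 chains, 500
adaptation, 2000 burn-in, thinning 8). Convergence is gated on the
potential scale reduction factor (< 1.1) and an effective-sample-size
floor (50) over all variance parameters, the scope effects and γ; the
individually weakly identified fixed-effect decomposition (global
intercept/trend vs. hierarchical means, covariate coefficients) is
monitored and reported but not gated, because the prevalence surface —
their identified sum — is what the posterior draws carry. Failures raise
a warning and are flagged in the returned diagnostics, never silently
ignored. Retained draws are transformed to prevalence surfaces for every
country, year, sex and age group in R from the monitored level surface,
age-spline coefficients and γ.

## Derived quantities

Age standardisation uses the WHO World Standard Population restricted to
ages 18+ and renormalised; the 18–19 weight takes 2/5 of the 15–19
standard weight and 80+ pools everything above 80 (the exact vintage and
18–19 handling are not fixed by the source material; the 2001 world
standard is used and the file is replaceable). Crude prevalence and counts
weight by the actual population. All summaries are computed per posterior
draw; intervals are the 2.5–97.5 percentiles.

The change in the number of adults with diabetes between t₀ and t₁
decomposes, with base-year weighting, into G = Σ(pop₁ − pop₀)·prev₀
(growth and ageing), P = Σpop₀·(prev₁ − prev₀) (prevalence change) and
I = Σ(pop₁ − pop₀)·(prev₁ − prev₀) (interaction), which sum to the total
change exactly. Shares are reported as each component over the component
sum — the convention under which the shares follow directly from the
component magnitudes regardless of how the totals were rounded. Note that
reversing the time points maps
G → −(G+I), P → −(P+I), I → I; only the total negates exactly.

The 2025 target assessment fits, per draw, an ordinary least-squares line
on the probit scale through the 2000–2014 age-standardised trajectory and
extrapolates to 2025 ("if post-2000 trends continue"); the probability of
meeting the target is the fraction of paired draws in which the projection
does not exceed the 2010 baseline. Ties count as met (the non-strict
inequality; the original convention is unstated). The per-draw OLS
projection is itself a documented stand-in — re-using the model's trend
parameters would be an alternative — and is configurable through the
window and target year arguments.

## Hold-out validation

`makeHoldoutSplit()` offers three schemes — a random fraction of
datapoints, whole studies, or whole countries — because no single
withholding protocol is canonical for this problem; whole-country
withholding is the hardest and most informative test.
Scoring compares the posterior-mean prevalence of each withheld stratum
(population-weighted over its age groups) with the observed prevalence, in
percentage points, and reports median error, median absolute error and the
share of observations inside the stratum's 2.5–97.5 posterior interval.
Observation-level coverage is expected below 95% because the observation
carries sampling noise the posterior interval does not include.

## Numerical choices and test scale

Degenerate inputs are rejected, not repaired: strata outside the world's
support, non-harmonised definitions reaching the model, mismatched age
groups in the decomposition, unpaired target draws, empty training splits.
Datapoints are canonically sorted inside the fitting routine, so results
are exactly invariant to input row order. All random number use flows from
explicit integer seeds through per-unit substreams.

The test suite runs the model at reduced scale: the recovery world uses 12
countries × 35 years × one sex with ~110 studies and 1000 retained draws
(the configuration also used by `scripts/acceptance.R`); property tests
use 2–4 country worlds with a few hundred draws. These sizes were chosen
so the whole suite exercises every stage, including ten independent
coverage-calibration fits, at desk scale. Known limitations: with two
chains and short runs the Rhat gate can flag marginal parameters on
unlucky seeds; covariate effects are identified only from within-country
non-trend variation (see above); and the generator's simplifications mean
real-data performance must be established separately.
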