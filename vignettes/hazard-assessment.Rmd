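---
title: "Stratified log-normal hazard assessment for arsenic in private water supplies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified log-normal hazard assessment for arsenic in private water supplies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwshazard)
```

## The model and its assumptions

Arsenic concentrations in groundwater-fed private water supplies (PWS)
are strictly positive, span several orders of magnitude, and are heavily
right-skewed.  Within a geological stratum (SBGC) we model the
concentration `X` of a randomly chosen dwelling's supply as log-normal:
`ln X ~ Normal(ln GM, σ²)`, with `GM` the geometric mean (µg/L) and `σ`
the standard deviation of natural-log concentrations.  The assumptions
this encodes:

* dwellings within a stratum are exchangeable — no spatial or
  within-supply correlation structure is modelled;
* the stratum label captures the systematic variation; residual
  variation is multiplicative noise;
* a single distribution describes treated and untreated supplies alike
  (the model is fitted to drinking-water concentrations as consumed).

One interpretation decision dominates everything downstream: the
quantity tabulated as *geometric standard deviation* in surveys of this
kind is here read as `sd(ln x)` itself, **not** `exp(sd(ln x))` and not
a base-10 quantity.  Only this reading makes the packaged per-stratum
parameters reproduce their published band probabilities (for stratum 04,
`(ln 10 − ln 1.213)/2.542 = 0.830`, upper tail 20.3%).  Z-scores are
ratio-invariant to the log base when used consistently, so a base-10
pipeline with `σ` in base-10 units would give identical probabilities;
natural logs are used throughout.

## From model to decisions

Band probabilities are normal-CDF differences at cut points 1, 5 and
10 µg/L; the top band (≥ 10 µg/L) is exceedance of the prescribed
concentration value (PCV).  For the continuous model the closed/open
status of a cut point carries zero probability; for *empirical* band
fractions the bands are closed on the left, so a measurement of exactly
10 µg/L counts as an exceedance.

Hazard ranks discretise the exceedance probability: rank 1 above 10%,
rank 2 for 5–10% (both edges included), rank 3 for 1–5% (1% included),
rank 4 below 1%.  All published examples sit away from the edges, so any
half-open convention reproduces them; the edge assignment here follows
the "more than 10%" / "less than 1%" phrasing of the rule.

Dwelling-count predictions multiply band probabilities by a per-stratum
supply count.  Regional totals are formed from *unrounded* per-stratum
expectations and rounded once at the end — rounding each stratum first
would inflate the 200-dwellings-per-stratum example from 96 to 97.
Counts round half away from zero (a count of 40.66 reports as 41).
`capture_fraction()` expresses a prioritisation policy: the share of
expected exceedances on strata whose rank falls in a chosen set.

```{r}
models <- cornwall_sbgc_params()
region <- predict_region(models, n_dwellings = 200)
region$total_rounded
round(capture_fraction(region, c(1, 2)), 3)
```

## Record resolution

Before any statistics, repeat measurements of one supply collapse to
their maximum (a worst-case exposure rule), and that value is ascribed
to every dwelling sharing the supply.  The operation is idempotent and
never lowers a dwelling's assigned concentration; dwelling counts are
unchanged, so shared supplies weight the fitted distribution by the
number of households exposed.

## Transformation selection

The ladder-of-powers search evaluates nine candidate transformations
(x³, x², x, √x, ln x, 1/√x, 1/x, 1/x², 1/x³) and scores each with the
D'Agostino–Pearson omnibus statistic `K² = Z(√b₁)² + Z(b₂)²`, the sum of
squared normalising transforms of sample skewness and kurtosis, referred
to χ²(2).  The rung with the largest p-value is selected; ties break
toward log, then identity.  K² is implemented from the published
normalising transforms; statistical packages sometimes apply a
Royston-style small-sample adjustment, and small numerical differences
from such variants are accepted.  The test needs n ≥ 20 for the kurtosis
normalisation to behave, and selection needs `min_n = 30` observations —
below that, or when no rung reaches `alpha = 0.05`, log-normality is
*assumed* and flagged (`assumed_default`), the standard fallback for
environmental concentration data.  The lower bound of 30 (the field
quotes "30 to 50") admits the mid-sized strata that were selected on in
the motivating survey.  Inverse-family rungs are not sign-negated; the
order reversal is irrelevant to a normality statistic.  Q–Q diagnostics
use plotting positions `(i − 0.5)/n`.

A practical note from simulation: when the coefficient of variation is
tiny, every power transform is near-affine and the nine p-values are
essentially exchangeable, so "which rung wins" is noise; the search is
informative only when the data vary enough for the rungs to differ.

## Between-stratum comparison

The decision flow tests homoscedasticity of log concentrations with two
robust Levene variants — absolute deviations from the group median
(Brown–Forsythe) and from the 10% trimmed mean (`floor(0.1 n)` removed
per tail; trimming affects the centring only).  Strata are treated as
homoscedastic only if **both** variants are non-significant, the
conservative combination of the two tests.  If homoscedastic, means of
log concentrations are compared with a pooled t-test (two strata) or
one-way ANOVA (more; a "t-test" across ten groups is undefined, so the
ANOVA generalisation is used and reported as such).  Otherwise the
Kruskal–Wallis rank-sum test (mid-ranks, tie-corrected) compares the
distributions; ranks are invariant under strictly increasing maps, so
raw and log concentrations give identical H.  Whether the variance tests
should see raw or log data is not dictated by the method description;
log is used, consistent with the comparison being of the log-transformed
distributions.

## Synthetic data: what it emulates and what it does not

`default_sim_config()` *is* the study design the analysis targets: ten
strata at the published `(GM, σ)` pairs and the published sample sizes
(140, 93, 11, 19, 73, 69, 66, 3, 18, 16 — 508 dwellings), LOD
0.02 µg/L, no shared supplies (the motivating survey reports no
shared-supply statistics; the `shared_supply_fraction` knob exists to
exercise record resolution).  Draws below the LOD are substituted **at**
the LOD with a censoring flag — not truncated, not halved — because the
published per-stratum minima equal the LOD exactly, indicating recorded
values were floored there.  Substituted values enter descriptive
statistics as-is; an LOD/2 convention can be emulated by passing a
different `lod`.

Per-stratum sub-seeds are derived as `(seed·48271 + i·30269) mod
(2³¹−1)`, so appending strata to a configuration never perturbs the
draws of earlier ones.

What passing tests on these simulations shows: the estimators recover
the generating parameters, band fractions converge to model
probabilities, and the decision flow detects the heteroscedasticity that
the published σ spread (0.885–2.542) implies.  What they cannot show:
robustness to volunteer-response bias, seasonality, treatment effects,
spatial clustering, or model misspecification in real surveys — none of
which the generator parameterises.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics (R type 7).
* `σ = 0` is a point mass at GM: all band probability falls in the band
  containing GM; exceedance at the threshold itself is 1 (the closed
  upper band).
* Probabilities sum to 1 to within 1e−12 by construction (telescoping
  CDF differences).
* Constant data: defined for fitting (σ = 0) but rejected by the
  normality test and Q–Q standardisation; identical values across all
  groups are a degenerate input for Kruskal–Wallis (tie divisor zero)
  and rejected.
* CSV numeric formatting defaults to 3 significant figures; JSON
  parameter files carry full precision.

## Problem sizes

The test suite and acceptance script use 10⁵-draw simulations for
convergence checks (binomial 3-SE bands), 20 seeds for the
heteroscedasticity behaviour of the default study, and 500 replicates of
a two-stratum null for the decision flow's type-I error, sizes at which
the checked bands are tight relative to the effects of interest.

## Known limitations

* The published empirical survey columns (e.g. the observed 6%
  exceedance among 508 dwellings) are not reproducible here: the raw
  survey microdata were never deposited, so empirical behaviour is
  covered by property checks on synthetic data instead.
* One published row resists exact reproduction: the n = 3 stratum's
  upper band cells are mutually inconsistent with its own printed
  parameters under any log base (its four cells sum to 100.04%); the
  package reproduces what the parameters imply.
* Confidence intervals for per-stratum GMs are not provided; with n as
  low as 3 they would be dominated by the interval method chosen, and
  the upstream method statement does not specify one.
* Strata are taken as labels on the input; deriving them (geological
  maps, mineralisation buffers, postcode attribution) is out of scope.
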