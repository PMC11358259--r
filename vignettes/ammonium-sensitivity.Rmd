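---
title: "Classifying plant ammonium sensitivity from biomass response ratios"
author: "ammsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant ammonium sensitivity from biomass response ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ammsens)
library(dplyr)
```

## The problem

Ammonium (NH4+) as the sole nitrogen source is toxic to many plant species,
while others — rice, maize, sorghum — tolerate or even prefer it. Because
tolerance varies continuously across species, cultivars and growth
conditions (in particular the pH of the nutrient solution), a single
screening experiment cannot rank species; what can is a quantitative
synthesis of the many published hydroponic experiments that grew the same
species on ammonium and on nitrate under otherwise equal conditions.

`ammsens` implements that synthesis as a reusable pipeline: an effect-size
statistic for ammonium sensitivity, organ-biomass aggregation, a
random-effects meta-analysis with bootstrap and publication-bias
diagnostics, pH stratification, association of pooled species effects with
ecological indicator values and nitrogen-transporter gene counts, and the
companion 15N tracer calculations used to compare uptake and root-to-shoot
translocation between contrasting species. A seeded synthetic-data
generator emulates each input, so every stage is validated against known
ground truth.

## The effect size: LnBR

For one study, species, cultivar, organ and solution pH, with mean biomass
$\bar{x}_{NH_4}$ under sole-ammonium and $\bar{x}_{NO_3}$ under sole-nitrate
nutrition, the effect size is the log response ratio

$$\mathrm{LnBR} = \ln\!\left(\frac{\bar{x}_{NH_4}}{\bar{x}_{NO_3}}\right),$$

negative when growth on ammonium is inferior. Its large-sample variance is
the delta-method approximation

$$\widehat{\mathrm{var}}(\mathrm{LnBR}) =
  \frac{SD_{NH_4}^2}{N_{NH_4}\,\bar{x}_{NH_4}^2} +
  \frac{SD_{NO_3}^2}{N_{NO_3}\,\bar{x}_{NO_3}^2},$$

the sum of the squared coefficients of variation of the two arm means.
Studies reporting SE instead of SD are normalized first
(`se_to_sd()`, $SD = SE\sqrt{n}$); arms with fewer than three biological
replicates are rejected at ingest, mirroring the inclusion rule of the
underlying systematic review. Biomass basis (fresh versus dry weight) is
*not* harmonized — source studies report either, no defensible conversion
exists, and the log ratio is invariant to any common per-study scale — so a
basis column, if present, is carried through ingest and output untouched
for stratified sensitivity checks.

**Accuracy of the variance formula.** The delta method is first order: the
neglected term grows like $c^4$ per arm, where $c$ is the coefficient of
variation of the arm *mean* ($c = CV/\sqrt{n}$). The test suite verifies the
formula against the Monte-Carlo variance of $\ln$(sample-mean ratio) at
$10^5$ resamples with replicate CVs of 0.10, where the second-order term is
several times smaller than the Monte-Carlo noise; at replicate CVs around
0.2 the $c^4$ term becomes detectable at that resolution. Users with very
noisy arms should treat the per-case variance as an approximation.

**Organ aggregation.** Whole-plant biomass is shoot + root; where stem and
leaf are reported separately, shoot = stem + leaf; for rosette-stage
species, leaf biomass alone stands in for the shoot. Variances add under
the working assumption that organ biomasses are independent (covariance
term set to zero); `aggregate_organs()` exposes the covariance as an
argument so the sensitivity of that assumption can be probed. The replicate
count of an aggregate is taken as the minimum of the part counts — the
parts come from the same plants, so the smaller arm bounds the information
— but downstream variance propagation uses the summed variance, never the
aggregate n, so this choice only affects bookkeeping.

## Random-effects pooling

Species (or cultivars) are pooled per organ and pH class under a
random-effects model, with the study as the random effect. The pH strata
split at 6.5, the usual optimum for nutrient availability in hydroponics:
`low` below 6.5, `high` at or above.

Between-study variance $\tau^2$ uses the DerSimonian–Laird moment
estimator,

$$\tau^2 = \max\!\left(0,\; \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),
\qquad w_i = 1/v_i,$$

with $Q$ the usual heterogeneity statistic. The choice of the moment
estimator follows the lineage of ecology meta-analysis software built on
method-of-moments random-effects pooling; a REML estimate (profile
restricted likelihood, `optimize()` on $\tau^2$) is available behind
`method = "REML"` and agrees with `metafor` to ~1e-5 in the cross-check
tests. The pooled estimate is the inverse-variance mean with weights
$w^*_i = 1/(v_i + \tau^2)$, and its confidence interval is
$\hat\theta \pm 1.96\,\mathrm{se}$ — the multiplier is 1.96 *exactly* at
the default level, matching the SD × 1.96 convention of the synthesis this
package operationalizes (other levels fall back to the normal quantile).
Replicate counts enter through each study's sampling variance; beyond
inverse-variance weighting no additional "number of studies" weight is
applied, since no operational definition of one exists — `forest_table()`
offers both unweighted (default) and weighted overall rows instead.

Groups with a single study are never pooled. They are carried in a separate
reported-only table with their per-study SD × 1.96 interval and excluded
from overall means, mirroring the practice of manually adding single-study
species to forest plots for context.

Numerical edge cases: zero sampling variances are floored at 1e-8 with a
warning so weights stay finite, except that a group of identical effects
with zero variances short-circuits to that common value with zero SE.
$\tau^2$ is truncated at zero.

**Bootstrap.** `bootstrap_pool()` resamples *studies* (the declared random
effect) with replacement, re-pools each resample and returns the percentile
2.5/97.5 interval; 1000 iterations by default, reproducible under an
explicit seed (each group in `meta_pool()` gets a seed derived from the
master seed). BCa corrections are deliberately not implemented — percentile
intervals are what the cross-validation this mirrors used. Across simulated
heterogeneous groups the bootstrap interval is narrower than the
variance-based interval in the large majority of cases (the acceptance
suite measures the fraction; ~90–96% across seeds), reproducing the
qualitative observation that variance-based intervals are the conservative
"worst case".

**Publication bias.** Rosenthal's fail-safe N:
$N_{fs} = \max(0, (\sum Z_i / z_\alpha)^2 - k)$ with $Z_i$ signed toward
the pooled direction and one-tailed $z_{0.05} = 1.645$ (Rosenthal's
original convention; rounding is half-away-from-zero before truncation at
zero). The conventional robustness flag is $N_{fs} > 5k + 10$. A
zero-variance study would give an infinite Z and is rejected with a
diagnostic rather than floored, since the statistic is a sum of per-study
evidence, not a weighted mean.

**Calibration.** Under the recovery conditions exercised by the acceptance
suite (500 groups of k = 30 studies, true effect −1.0, $\tau^2 = 0.1$,
per-study variances 0.02–0.1) the pooled estimate is unbiased to well
within ±0.05 and the nominal 95% interval covers the truth in roughly
93–95% of runs — the familiar mild anticonservatism of DL intervals at
moderate k, inside the 93–97% band the suite asserts.

## Trait association

Species-level pooled LnBR (per organ, pooled across cultivars) is joined to
a trait table — Ellenberg indicator values for nitrogen requirement (N) and
soil reaction (R), both ordinal 1–9; spread capacity (number of countries
where the species is recorded as invasive); and counts of NPF, NRT2, AMT1
and AMT2 nitrogen-transporter genes. Missing trait values stay missing
(never zero-filled) and each regression is complete-case with its n
reported.

Associations are ordinary least squares per predictor (`linear_assoc()`),
reporting slope, intercept, $r^2$ (squared Pearson correlation) and the
two-sided p of the zero-slope test; p-values are reported raw, without
multiple-testing correction, and fits are unweighted by default with an
inverse-variance weighting option (`weight_var`), since the source practice
does not state a weighting. The PCA (`pca_traits()`) standardizes variables
to unit variance — Ellenberg ordinals, country counts and log-ratios are on
incommensurate scales, so the correlation-matrix PCA is the defensible
choice — and reports loadings, scores and percent variance per component
(summing to 100 by construction, verified to 1e-9 against a direct
eigendecomposition).

## 15N tracer calculations

Labeling assays incubate plants in 15N-enriched ammonium or nitrate
solution for short times (the canonical design uses 3, 7, 15 and 30 min)
and measure atom% 15N, total %N and dry weight per organ. The package
computes, per organ,

$$\mathrm{excess\ ^{15}N\ (g)} =
  \frac{\mathrm{at\%}_t - \mathrm{at\%}_{t_0}}{100}
  \cdot \frac{\%N}{100} \cdot DW_g,$$

an excess-mass formulation that is dimensionally consistent regardless of
whether the instrument reports atom% or delta notation —
`delta_to_atom_pct()` converts from per-mil delta-15N using the
atmospheric-N2 standard ratio 0.0036765 (0.36630 atom% at natural
abundance). The root-to-shoot translocation fraction is the shoot share of
the plant's excess, shoot/(shoot + root), so shoot and root shares sum to
one by construction. Slightly negative excesses (instrument noise at
natural abundance) are kept and flagged, not clamped; a partition whose
total excess is non-positive is an error, since the fraction is then
undefined. Uptake rates come from an OLS fit of plant-total excess on time
(`uptake_trend()`).

## The synthetic-data generator

`sim_config()` fixes the ground truth once; the three generators are pure
functions of it (all randomness flows from the master seed through
per-generator offset streams, so identical configs give byte-identical
tables).

* **Study sets** (`simulate_study_set()`): species-level true effects
  $\theta_s \sim N(-0.6, 0.6^2)$ by default — most species grow worse on
  ammonium, a few tolerate it, spanning the range observed across crops;
  study effects $\theta_i \sim N(\theta_s, \tau^2)$ with $\tau^2 = 0.1$;
  2–6 studies per species (the meta-analysis inclusion floor is 2);
  nitrate-arm means lognormal around 1 g (root) and 3 g (shoot); replicate
  counts 3–6 with within-arm CV 0.15, typical of hydroponic biomass data;
  half the studies at low pH; a quarter of rows report SE rather than SD so
  normalization is exercised. Replicates are lognormal
  ($\sigma^2 = \ln(1 + CV^2)$), keeping biomass strictly positive — the
  domain requirement of the log ratio.
* **Trait tables** (`simulate_traits()`): Ellenberg scores are linear in
  $\theta_s$ with noise chosen so the latent relation explains 30% of the
  score variance, then rounded and clipped to the 1–9 ordinal scale; gene
  counts are log-link Poisson in $\theta_s$ (NRT2 decreasing — ammonium-
  sensitive species carry more high-affinity nitrate transporters; AMT2
  increasing; NPF and AMT1 flat). The default species count for
  trait-recovery experiments is 14, the realistic size of a gene-count
  panel.
* **Tracer courses** (`simulate_tracer()`): plant-total excess grows
  linearly at 1e-5 g/min, split shoot:root at a translocation fraction of
  0.3, with multiplicative Gaussian organ noise (5% default) and exact
  natural-abundance baselines at time zero.

What the generator does *not* emulate: organ-level covariance of biomass
(the pipeline assumes independence, so simulating it would only probe the
stated assumption), digitization error from figure extraction, non-linear
uptake saturation at long incubation times, and publication bias itself.
Passing tests therefore demonstrate that the statistics recover the truth
under the declared model, not that the model captures every pathology of
extracted literature data.

## Validation strategy and problem sizes

The test suite checks every closed-form statistic against independent hand
arithmetic at 1e-12, cross-checks DL/REML pooling against `metafor`,
and runs parameter-recovery simulations at the scales chosen for stable
Monte-Carlo estimates on a laptop: 500 pooled-recovery groups (k = 30), 500
end-to-end simulate→ingest→pool coverage runs, 200 bootstrap-vs-variance
groups at 1000 iterations each, 500 trait-table draws against a 2e5-row
generative oracle, and 500 noisy tracer courses. `scripts/acceptance.R`
recomputes the same quantities from scratch under a caller-supplied seed.

Known limitations: the delta-method variance degrades as $c^4$ (above); DL
intervals are mildly anticonservative at small k; the small-sample $r^2$ of
a 14-species regression is biased upward by roughly $(1-\rho^2)(1-2\rho^2)/n$
relative to the population value, which is why the trait-recovery check
compares against a large-n oracle with a ±0.05 band rather than the nominal
0.30; and fail-safe N inherits every caveat of Rosenthal's method — it is a
robustness heuristic, not an estimate of missing studies.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
records <- simulate_study_set(cfg)

effects <- records |>
  validate_study_records() |>
  se_to_sd() |>
  pair_comparisons() |>
  compute_effects()

fit <- meta_pool(effects, by = c("species", "organ", "ph_class"),
                 iterations = 1000, seed = 42)
tidy(fit)          # pooled groups: estimate, tau2, Q, fail-safe N, CIs
forest_table(fit)  # forest rows + OVERALL LOW / OVERALL HIGH
autoplot(fit)      # forest plot

traits <- simulate_traits(cfg)
species_fit <- meta_pool(effects, by = c("species", "organ"), iterations = 0)
merged <- merge_traits(tidy(species_fit), traits)
assoc_table(merged[merged$organ == "shoot", ],
            c("ellenberg_n", "ellenberg_r", "nrt2_count", "amt2_count"),
            response = "estimate")
```
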