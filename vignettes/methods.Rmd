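---
title: "Methods: linking land-cover change to pollinator community change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking land-cover change to pollinator community change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollscape)
```

## The problem

Volunteer recording schemes hold a century of bee and wasp occurrence
records, and digitised historical land-use surveys now make it possible to
ask whether the places that changed most also changed most biologically.
Two obstacles make the naive comparison meaningless: sampling effort
differs enormously between a historical and a current recording period, and
land-cover "change" must be reduced to site-level predictors that a
regression can use. `pollscape` packages both halves — effort-corrected
change estimation per site, and landscape change metrics at multiple
spatial scales — together with the weighted regression machinery that
links them, and a synthetic-data generator that provides ground truth for
every stage.

## Landscape metrics

Both periods are categorical rasters on a shared grid and legend (a broad
8+1-class scheme; `reclassify()` collapses a finer contemporary legend onto
it, with an explicit "other" default). Around each focal site,
`build_zones()` thresholds the Euclidean distance from the site to build
buffer rings (the field convention is 1, 2, 5 and 10 km; rings exclude the
site, and a cumulative-disc mode exists for sensitivity checks). Within
each zone:

* `percent_change()` reports per-class cover change in **percentage points
  of the zone**, so the changes sum to zero — relative change would not
  conserve and would explode for rare classes. Cells that are nodata in
  either period are excluded symmetrically.
* `weight_change()` multiplies each class's change by a pollinator
  suitability score in [0, 1] (an input: expert-derived in real use,
  generated synthetically here); the sum over classes is the
  change-in-habitat-suitability index.
* `adjacency_matrix()` tallies rook-adjacent (4-neighbour) cell pairs by
  unordered class pair, both cells inside the zone, each pair counted
  once; `edge_change()` differences the two periods. Some landscape-metric
  software double-counts like-class adjacencies; a `double_count_like`
  switch reproduces that convention, and period differences are invariant
  to it. Rook rather than queen adjacency is the default because an edge
  shared by two cells is the natural unit of "edge habitat"; the
  neighbourhood convention is exposed rather than hidden.

`screen_collinearity()` computes Pearson correlations between candidate
predictors across sites and flags significant pairs (α = 0.05) as
forbidden — cover changes are compositional, so strong negative
correlations (heathland loss appearing as woodland gain) are expected and
must not co-occur in one model.

## Richness change

Each site × period reduces to a reference sample: abundances `x_i`, effort
`n`, observed richness `S_obs`, singletons `f1`, doubletons `f2`.

* Interpolation (`rarefy()`):
  `S(m) = S_obs − Σ_i C(n − x_i, m) / C(n, m)`, computed on the log scale
  for stability. This is the exact expectation over all `C(n, m)`
  subsamples (the test suite checks it against exhaustive enumeration up
  to `n = 12`, and against an independent library implementation).
* Extrapolation (`extrapolate()`): the Chao1 unseen-species estimate
  `f̂0 = ((n−1)/n) f1²/(2 f2)` (with the `f1(f1−1)/2` fallback when
  `f2 = 0`) drives
  `S(n + m*) = S_obs + f̂0 (1 − (1 − f1/(n f̂0 + f1))^{m*})`.
  Extrapolation is refused beyond 3× the observed effort — beyond short
  range the curve is pure `f̂0` speculation — and `f1 = 0` pins the curve
  at `S_obs`.
* Comparison (`richness_change()`): both periods are evaluated at
  `n_cmp = min(max(n1, n2), 3 min(n1, n2))`. The spec of the source
  analysis fixes the ratio-at-common-effort and the 3× ceiling but not the
  common effort itself; this rule uses as much of the larger sample as the
  ceiling allows, which maximises information while never extrapolating
  past the cap. The effect size is `ln[S2(n_cmp)/S1(n_cmp)]`.
* Bootstrap: records are resampled with replacement within each period
  (effort fixed), B = 1000 by default. The reported logratio is the
  standard bias adjustment `2·θ̂ − mean(θ*)` — resampling systematically
  loses rare species, and the richer, less-completely-sampled period loses
  relatively more, so the adjustment counteracts the singleton/doubleton
  sensitivity of the plug-in estimate. The bootstrap variance feeds the
  inverse-variance weights downstream. The resampling unit (individual
  records) and the bias-correction form are declared package choices; the
  upstream method they emulate does not pin them down.
* `site_filter()` excludes sites with fewer than 5 species or 10 records
  in either period, or a ≥ 10-fold effort imbalance (strictly: a ratio of
  exactly 10 fails). Filtered sites are excluded from both the richness
  and the composition analyses.

## Composition change

For species shared between periods, `U` and `V` are their total relative
abundances in the historical and current samples. The composition-change
index is

&nbsp;&nbsp;&nbsp;&nbsp;`SCC = 1 − UV / (U + V − UV)`

the abundance-based Jaccard-type dissimilarity: 1 when no species are
shared, 0 for identical lists, symmetric and decreasing in each argument.
The displayed equation of the source analysis is unreadable in the
available text; this functional form is a declared reconstruction,
constrained by the stated U/V semantics and by both printed boundary
anchors, which it reproduces exactly. The incidence-only
`beta_sim = min(b, c)/(min(b, c) + a)` is always reported alongside as an
uncorrected cross-check, and a bias-corrected U/V variant (a Chao-style
unseen-shared-species correction built from cross-period singletons and
doubletons, clamped to 1) is selectable; the two variants coincide
whenever no shared species is rare in the other period.

## Models

`meta_regress()` fits the random-effects meta-regression
`y_i = x_i'β + u_i + e_i`, `u_i ~ N(0, τ²)`, `e_i ~ N(0, v_i)` with the
bootstrap variances as known `v_i`: sites with more reliable richness
estimates carry more weight. τ² is estimated by REML (profiled
numerically; ML and DerSimonian–Laird are selectable), coefficients by
GLS with Wald z tests. **VAF** = `100 (τ²_null − τ²_model)/τ²_null` is the
share of between-site heterogeneity absorbed by the moderators; it is
reported raw (possibly negative) and flagged undefined when the null has
no heterogeneity.

`stepwise_select()` performs backward elimination by AICc from the
constrained full model. AICc rather than AIC because site counts are small
(the correction term is material at k ≈ 14); comparisons between models
with different moderators use the ML likelihood (REML likelihoods are not
comparable across fixed-effect structures), and the final model is refit
by REML. Three constraint families hold in every evaluated candidate:
forbidden (collinear) pairs never co-occur — when they bisect the
candidate set, every maximal admissible subset is searched and the best
final AICc wins; two-way interactions are only retained alongside both
mains; and cover-change versus edge-change families, and different
spatial scales, are fitted in separate models by construction (the caller
passes one family × scale per call). Ties break deterministically:
smaller model first, then lexicographic term name.

SCC has no per-site standard error, so `glm_composition()` models it with
an ordinary Gaussian identity-link linear model through the same selection
engine. A beta regression would respect the [0, 1] support but is a
deliberate non-goal: the reference analysis used a Gaussian GLM, and the
package mirrors it.

`sampling_bias_check()` regresses the logratios on `ΔR = ln(n2/n1)`
(inverse-variance weighted). If the slope is significant at α = 0.05 the
effects are replaced by partial residuals (fitted ΔR component removed,
intercept retained); the sampling variances are kept as supplied — the
upstream analysis does not state how the adjustment should propagate into
the weights, and leaving them unchanged is the conservative reading
(flagged in the output). `morans_i()` screens any site-level quantity for
spatial autocorrelation with row-normalised inverse-distance weights
(expected value −1/(k−1), normal-approximation p; constant fields are
reported undefined, duplicate coordinates offset by a warning epsilon).

## The synthetic world

The generator states a world rather than tuning one:

* **Landscape**: 9 classes (8 broad historical-survey-like classes plus
  "other") on a 200×200 grid of 100 m cells; 10 disc-shaped sites of
  500 m radius dominated (70%) by the focal heathland-analogue class;
  rings at 1 and 2 km. Between periods exactly `round(f·n)` cells per zone
  are reassigned to a different class (f = 0.2 in sites, 0.1 in rings by
  default); sites are placed so zones never overlap, keeping per-zone
  change exact, and cells outside every zone are untouched. Real sites
  are irregular polygons, not discs, but no estimator contract depends on
  shape.
* **Communities**: a pool of 100 species with Fisher log-series
  abundances (α = 50, the classic fit to insect record data — it yields
  realistic singleton/doubleton loads, which is what exercises the
  bootstrap and Chao corrections). The period-1 community is a random
  pool subset; period 2 keeps a fraction `1 − turnover_frac` of it and
  refills to `richness_ratio` times the period-1 richness from unused
  pool species (replace-then-redraw, which controls the shared-species
  fraction directly). The period-1 size is the largest that lets this
  construction fit in the pool, `S1 = ⌊S_pool/(1 + ρ − (1−t)·min(1, ρ))⌋`.
  Records are individual occurrences drawn multinomially (500 per period
  by default). Ground-truth species sets ride along for testing.
* **Coupled world** (`generate_world()`): 30 sites in which, a priori,
  only urban cover change in ring 1 drives richness
  (`logratio = 0.05 · Δ%urban`) and only grassland–arable edge change at
  the site drives turnover (`turnover = 0.5 + 0.05 · ΔA`, clamped to
  [0.05, 0.95]), with per-site heterogeneity injected through the swap
  fractions and swap-target weights. These effect sizes span roughly ±1
  logratio unit and ±0.45 turnover across sites — a driver that genuinely
  dominates sampling noise at 400 records/period — and were fixed when the
  world was designed, not adjusted to test outcomes.

What a green test does establish: the estimators are exact against
enumeration oracles, conservation laws hold, configured richness ratios
are recovered within 10% at survey-scale effort, and the model-selection
chain finds a dominant known driver with the right sign in ≥ 80% of
worlds. What it does not establish: behaviour under real-world record
clustering (visit lists, observer heterogeneity), taxonomic drift, or
spatially autocorrelated land-cover change — the generator draws records
independently and swaps cells independently, so those failure modes are
outside its reach.

## Numerical choices and degenerate inputs

* Rarefaction uses `lchoose` differences; terms with `n − x_i < m` are
  exactly zero.
* τ² is profiled on `[0, max(10·var(y), max v_i)]`; the boundary τ² = 0 is
  admitted explicitly (and skipped when any `v_i = 0` makes the boundary
  objective undefined — with all `v_i = 0` the fit collapses to OLS, which
  the tests assert).
* Zero-variance predictors are dropped with a warning before screening;
  a zero-variance SCC response short-circuits to the intercept-only model.
* Degenerate bootstrap (all replicates identical) reports variance 0 with
  a warning rather than failing.
* Empty buffer rings (site touching the grid edge, sub-cell radii) are
  flagged, not fatal; all-nodata zones are errors.
* All stage randomness derives from one master seed via a deterministic
  label hash (< 2³¹), so stages rerun in isolation reproduce the
  orchestrated run bit for bit.

## Known limitations

* No GeoTIFF I/O (no capable dependency in the supported stack); rasters
  travel as ESRI ASCII grids with a legend sidecar.
* No coverage-based rarefaction or Hill numbers beyond q = 0; no
  between-site ordination; no spatial random effects — all deliberate
  non-goals of the scope this package implements.
* The bias-corrected shared-abundance variant is an interpretation of the
  Chao-style correction (documented in code); the plug-in variant is the
  default and the two agree except in rare-shared-species regimes.
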