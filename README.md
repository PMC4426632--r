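# pollscape

Tools for asking whether multi-decadal **land-cover change** around a set of
focal sites explains observed change in **pollinator (bee and wasp) species
richness and community composition**, when the biological record is
heterogeneous volunteer occurrence data with wildly unequal sampling effort
between periods.

The package implements the full analysis chain as reusable, tested pieces:

1. **Land-cover change** (`percent_change()`, `weight_change()`,
   `adjacency_matrix()`, `edge_change()`): per-class percentage-point cover
   change and cell-adjacency (edge-habitat) change from paired categorical
   rasters, at the site and in buffer rings outside it (`build_zones()`),
   with per-class pollinator suitability weighting.
2. **Richness change** (`rarefy()`, `extrapolate()`, `richness_change()`):
   individual-based rarefaction
   `S(m) = S_obs − Σ_i C(n−x_i, m)/C(n, m)` joined to Chao1-style
   extrapolation
   `S(n+m*) = S_obs + f̂0 [1 − (1 − f1/(n f̂0 + f1))^{m*}]`,
   capped at 3× the observed effort. Both periods are scored at a common
   effort `n_cmp = min(max(n1,n2), 3·min(n1,n2))`; the effect size is the
   log ratio `ln[S2(n_cmp)/S1(n_cmp)]` with a bootstrap bias adjustment and
   variance. A data-quality filter (`site_filter()`) drops sites with
   < 5 species, < 10 records, or a ≥ 10-fold effort imbalance.
3. **Composition change** (`shared_abundance()`, `scc()`, `beta_sim()`):
   the species-composition-change index `SCC = 1 − UV/(U + V − UV)`, where
   `U` and `V` are the shared species' relative abundances in each period
   (plug-in or bias-corrected); `SCC = 1` with no shared species, `0` for
   identical lists. The incidence-only βsim is reported alongside.
4. **Models** (`meta_regress()`, `vaf()`, `stepwise_select()`,
   `glm_composition()`, `sampling_bias_check()`, `morans_i()`):
   inverse-variance random-effects meta-regression (REML τ², Wald tests,
   AICc) for the richness logratios; the percentage of heterogeneity
   accounted for (VAF); constrained backward stepwise AICc selection
   (collinear predictors barred from co-occurring, edge and cover families
   and different spatial scales kept in separate models); a Gaussian GLM
   for SCC; a ΔR = ln(n2/n1) residual effort-bias check with partial
   residuals; and a Moran's I spatial screen.
5. **Synthetic data** (`landscape_config()`, `generate_landscape()`,
   `community_config()`, `generate_assemblages()`,
   `generate_suitability_table()`): paired rasters, sites, rings,
   suitability scores and two-period log-series occurrence records with
   *known* ground-truth change, so every stage is testable end to end
   without any external data. `run_pipeline()` orchestrates the whole chain
   under one seed; `generate_world()`/`analyze_world()` build a coupled
   world in which known drivers can be recovered.

## Worked example

```r
library(pollscape)

cfg <- landscape_config(seed = 1)          # 200x200 cells, 10 sites, 9 classes
ccfg <- community_config(n1 = 400, n2 = 480, turnover_frac = 0.3,
                         richness_ratio = 1.1)
res <- run_pipeline(cfg, ccfg, seed = 1, B = 200)

res$richness[1, c("site", "n_cmp", "x1_hat", "x2_hat", "logratio", "var_logratio")]
#> # A tibble: 1 × 6
#>   site    n_cmp x1_hat x2_hat logratio var_logratio
#>   <chr>   <int>  <dbl>  <dbl>    <dbl>        <dbl>
#> 1 site_01   480   63.7     71    0.101      0.00264

res$composition[1, c("site", "u", "v", "scc", "beta_sim")]
#> # A tibble: 1 × 5
#>   site        u     v   scc beta_sim
#>   <chr>   <dbl> <dbl> <dbl>    <dbl>
#> 1 site_01 0.735 0.521 0.562    0.355
```

Here `site_01`'s 400 historical and 480 current records are compared at a
common effort of 480 individuals (the historical curve extrapolated within
its 3× cap): estimated richness rose from ~64 to 71 species
(logratio 0.101 ± 0.051), while 56% of the assemblage's abundance-weighted
composition turned over. `res$models` then holds the constrained stepwise
meta-regression/GLM fits of these responses on the per-zone land-cover
predictors (one model per zone, e.g. `richness_cover_ring_1000m`), and
`res$bias_check` reports whether a residual sampling-effort signature had
to be removed (here the check is skipped: equal design efforts give a
constant ΔR).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the installed package's full synthetic pipeline (landscape, change
metrics, richness, composition, model selection) and the coupled
driver-recovery world under the given seed, then writes the result JSON to
`--out`.
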