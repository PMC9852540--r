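# dieldecline

Comparative analysis of mammalian population decline across diel niches
— the parts of the 24-hour cycle in which species are physically active
(nocturnal, crepuscular, cathemeral, diurnal). Because humans are
predominantly diurnal, pressures such as harvesting and human–wildlife
conflict plausibly fall hardest on day-active species; `dieldecline`
provides the full workflow for testing that idea on an assemblage of
species, for macroecologists and conservation scientists working with
Red List style trait tables, posterior samples of phylogenies and
presence rasters.

## What it computes

* **Classification** (`classify_trends()`, `build_threat_sets()`):
  population-trend classes with provenance — a known Red List trend
  wins; otherwise threatened-category species (NT–CR) are classed
  declining (the *category rule*, justified by
  `category_trend_concordance()`); otherwise literature-derived trends;
  otherwise unclassified — plus ten-category threat sets that
  distinguish "no known threats" from "threats unknown".
* **Phylogenetic regressions** (`phylo_glm()`): decline (0/1) on diel
  niche by penalised-likelihood phylogenetic logistic regression
  (logistic MPLE), and threat counts on niche by a phylogenetic Poisson
  GEE. Both use the working correlation

  `R_ij(a) = exp(-a d_ij) (1 - e^{-2a t_ij}) / sqrt((1 - e^{-2a T_i})(1 - e^{-2a T_j}))`

  — the fixed-root OU transform of the Brownian tree covariance, with
  the signal parameter `a` estimated from the data; Firth penalisation
  keeps the logistic estimates finite under separation. Fits are classed
  S3 objects with `print`, `summary`, `coef`, `vcov`, `predict`,
  `residuals`, `simulate` and `plot` methods.
* **Tree-ensemble robustness** (`fit_ensemble()`, `run_study()`,
  `run_sensitivity()`): every model repeated over `B` trees sampled from
  a posterior ensemble; reported as mean coefficient, SD, the fraction
  of repetitions with p < 0.01 and a tier (`###` ≥ 90%, `##` ≥ 75%,
  `#` ≥ 60%), with the published sensitivity variants built in.
* **Spatial layers** (`richness_raster()`,
  `decline_proportion_raster()`): per-cell niche richness and the
  proportion of a niche's species declining from each major threat on an
  equal-area grid (EASE-Grid 2.0, 96.5 km cells), with low-richness
  masking and per-country non-decline overrides; rasters are exchanged
  as plain-text ESRI ASCII grids.
* **Synthetic data** (`synth_config()`, `sim_bundle()`): a generator
  producing complete study-shaped inputs (birth–death trees, Mk-evolved
  niches, decline with phylogenetic signal, niche-dependent threats, toy
  ranges) with ground truth retained, so the whole pipeline is testable
  offline.

## Worked example

```r
library(dieldecline)

cfg   <- synth_config(n_species = 400, seed = 11, n_trees = 5)
tree  <- sim_tree(cfg)
trees <- sim_ensemble(tree, cfg)
rec   <- sim_traits_and_trends(tree, cfg)
rec   <- filter_analysis_set(rec)   # drop marine / fossorial species
rec   <- impute_niche(rec, tree)    # Mk imputation of missing niches
rec   <- classify_trends(rec)
rec   <- build_threat_sets(rec)

niche_decline_table(rec)
#>    diel_niche n_total n_declining percent_declining
#> 1   nocturnal     230          62              27.0
#> 2 crepuscular      12           8              66.7
#> 3  cathemeral      45          10              22.2
#> 4     diurnal      88          40              45.5

dat <- transform(subset(rec, !niche_imputed & !is.na(diel_niche)),
                 declining = as.integer(trend_class == "declining"))
fit_ensemble(declining ~ diel_niche, dat, trees,
             family = "binomial", B = 5, seed = 2, model_id = "decline")
#> Ensemble model 'decline': 5/5 converged fits, n = 363
#>                   term mean_coef sd_coef frac_p_lt_001 tier
#>            (Intercept)    -1.035   0.001             1  ###
#>  diel_nichecrepuscular     1.555   0.003             0
#>   diel_nichecathemeral    -0.067   0.003             0
#>      diel_nichediurnal     0.836   0.004             1  ###
#> mean pseudo-R2: 0.0391
```

The table gives each niche's size, decliner count and percent declining
(half-up, one decimal; unclassified-trend species stay in the
denominator). The ensemble summary shows, for each niche contrast
against the nocturnal baseline, the mean log-odds coefficient across the
five trees, its across-tree SD, the fraction of repetitions significant
at p < 0.01 and the robustness tier: here decline risk is credibly
elevated in diurnal species (positive coefficient, `###`), while the
small crepuscular group's large coefficient is not a robust effect.
`run_pipeline(config, outdir)` chains all stages — simulate, classify,
fit, sensitivity, map — writing CSV/raster outputs and a JSON manifest
with the full filter-count audit trail; a thin command-line wrapper
lives at `inst/scripts/dieldecline.R`.

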