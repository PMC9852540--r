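---
title: "Models and design choices in dieldecline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in dieldecline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dieldecline)
```

## The scientific question

Most anthropogenic pressures are not uniform over the 24-hour cycle:
people hunt, farm, travel and build mostly by day. A mammal's *diel
niche* — whether it is nocturnal, crepuscular (twilight-active),
cathemeral (day and night) or diurnal — therefore plausibly modulates its
exposure to habitat loss, harvesting, human–wildlife conflict and the
other major drivers of population decline. `dieldecline` implements the
full comparative workflow for asking that question across a species
assemblage: rule-based classification of population trends and threats
from Red List style inputs, phylogenetic regressions of decline and
threat burden on diel niche, repetition of every model over a posterior
sample of phylogenies, and equal-area mapping of proportional declines.

Because the real inputs (a curated trait database, a 1000-tree posterior
supertree sample, per-species presence rasters) are large external
downloads, the package ships a first-class synthetic generator that
produces complete study-shaped inputs with known ground truth. Every
stage of the pipeline is exercised and tested against those synthetic
inputs.

## Classification rules

`assign_trend()` maps each species to *declining*, *non-declining* or
*unclassified*, with recorded provenance, by a fixed precedence:

1. a known Red List population trend wins (*decreasing* → declining;
   *stable*/*increasing* → non-declining);
2. otherwise, species in a threatened category (NT, VU, EN, CR) are
   classed declining — the *category rule*, justified empirically by
   `category_trend_concordance()`, the fraction of known-trend threatened
   species that are in fact decreasing (above 0.9 in real Red List data);
3. otherwise a literature-derived trend is used, if available;
4. otherwise the species remains unclassified.

A known stable trend therefore beats the category rule: a stable
Critically Endangered species is non-declining. Unclassified species
stay in denominators of descriptive summaries (they are members of their
niche), while their treatment in regressions is a mode:
`unclassified_mode = "code_zero"` (default) codes them 0, `"drop"`
removes them. The choice is exposed because assemblage-level datasets
rarely make the distinction explicit, and the sensitivity machinery can
run both.

Threats are ten binary flags per species (habitat loss, harvesting,
conflict, climate change, non-native species, pollution, hybridization,
prey depletion, disease, inbreeding). All-NA flags mean *threats
unknown*, which is distinct from a known empty threat set; a mix of NA
and 0/1 for one species is rejected as an ambiguous knowledge state.
Threat counts may range 0–10 by contract, even though observed counts in
real data rarely exceed 6. Per-threat models are only fitted for threats
affecting at least 50 declining species (`min_threat_n`), because rarer
threats give unstable logistic fits.

Marine and highly/fully fossorial species are excluded before any
analysis (they rely on different light cues), and species whose diel
niche had to be imputed are excluded from all regressions to avoid
circularity, while keeping their niche for maps and summaries.

Reported percentages are rounded half-up to one decimal
(`round_half_up()`), the usual presentation convention; R's default
round-half-even would print 39.85 as 39.8.

## The phylogenetic regressions

Both model families are fitted by `phylo_glm(formula, data, tree,
family)` and share one working-correlation family. Let `C` be the
Brownian shared-path covariance of the tree (`build_vcv()`), rescaled to
unit depth, `t_ij` the shared root-to-MRCA time, `T_i` tip depths and
`d_ij` the patristic distance. The correlation used is the fixed-root
Ornstein–Uhlenbeck transform

    R_ij(a) = exp(-a d_ij) * (1 - exp(-2 a t_ij)) /
              sqrt((1 - exp(-2 a T_i)) (1 - exp(-2 a T_j)))

with signal parameter `a` searched on a log scale over [0.01, 50]. The
two limits are interpretable: `a -> 0` recovers the Brownian correlation
`t_ij / sqrt(T_i T_j)` and `a -> Inf` the identity. On a star phylogeny
(`t_ij = 0`) the correlation is the identity for *every* `a`, so both
models reduce exactly to their non-phylogenetic counterparts — a
property the test suite exploits as an oracle.

**Binary decline models (logistic MPLE).** Coefficients solve the
penalised estimating equations

    X' Δ V(a)^{-1} (y - μ) + b(β) = 0,   V = A^{1/2} R(a) A^{1/2},

with logit link (`Δ = A = diag(μ(1-μ))`) and `b(β)` the Firth
bias-reduction term `0.5 ∇ log det(X' Δ V^{-1} Δ X)`. With identity
correlation this is exactly Firth-penalised logistic regression, which
guarantees finite estimates under the quasi-separation that small niches
(crepuscular decliners especially) produce. The signal parameter
maximises the Gaussian profile pseudo-likelihood of the standardised
working residuals; β and `a` are alternated to joint convergence
(score norm below 1e-8, `a` stable to 1e-5 on the log scale). Hitting
the *upper* `a` bound is the independence limit — a well-defined Firth
fit — and is accepted as converged; hitting the lower bound with a
still-improving profile flags non-convergence.

**Threat-count models (Poisson GEE).** Same estimating equations with
log link, `A = diag(μ)` and no penalty term. The default working
correlation (`corstr = "ou"`) estimates the decay `a` from Pearson
residuals exactly as above. This choice is deliberate: the phylogeny is
a *single* cluster, so no sandwich variance estimator exists, and the
honest alternative is to let the data set the working correlation.
Imposing the full Brownian correlation (`corstr = "brownian"`, kept as
an option) produces strongly anticonservative model-based standard
errors whenever the residuals carry little phylogenetic signal — in
simulation, 2-SE coverage of true niche effects fell near 50–65%,
against 92–98% with the estimated-decay correlation. Standard errors
are model-based, scaled by the Pearson dispersion `φ` (reported as the
fit's working-correlation scale).

**Inference and fit summaries.** p-values are two-sided Wald on the
model-based SEs. The pseudo-R² is McFadden's `1 - l1/l0` on the working
(independence) likelihood, with the intercept-only null evaluated at the
full model's estimated signal parameter so the comparison is between
nested mean structures under one correlation; a Nagelkerke-style variant
is also returned. Because weighted-score fits do not maximise the
independence likelihood, the ratio can dip trivially below zero and is
clipped at 0.

## Tree-ensemble repetition and robustness tiers

`fit_ensemble()` repeats a model over `B` trees (default 100, or the
ensemble size if smaller) sampled *without replacement* under a recorded
seed, then reports per-term mean coefficient, sample SD (n−1
denominator), the fraction of repetitions with p < 0.01, and a tier:
`###` for ≥ 0.90, `##` for [0.75, 0.90), `#` for [0.60, 0.75). The
fraction is computed over converged fits; non-converged fits are dropped
with a warning and counted, and a summary with fewer than `B/2`
converged fits is flagged unreliable. `run_study()` drives the three
model families (decline for all analysis species, threat count for
decliners with known threats, one per-threat decline model per selected
threat) and `run_sensitivity()` the four published robustness variants
(primates / non-primates, excluding literature-derived trends, and
re-deriving decline from threat status: VU/EN/CR declining, LC/NT not).

## Mk imputation of diel niche

`fit_mk()` fits an equal-rates (optionally all-rates-different) Mk model
by Felsenstein pruning with a uniform root prior; missing tips enter
with all-ones partial likelihoods. Marginal posteriors at missing tips
come from a standard up–down pass, and `impute_tips()` assigns the
maximum-posterior state, breaking exact ties by the fixed niche order
(nocturnal, crepuscular, cathemeral, diurnal) and flagging them. The
pruning likelihood is tested against exhaustive enumeration of all
ancestral-state assignments on small trees, and the ML rate against an
independent implementation (`ape::ace`).

## Spatial layers

Rasters live on an equal-area grid (`grid_spec()`; default cell 96.5 km
on the cylindrical equal-area EASE-Grid 2.0, EPSG:6933), with cells
indexed row-major from the upper-left corner. Layers are exchanged as
ESRI ASCII grids — a plain-text raster format readable by GDAL, QGIS and
ArcGIS — with the CRS identifier in a JSON sidecar.

`decline_proportion_raster()` computes, per cell, the fraction of a
niche's species that are declining from a given threat. The default
assumption is that a declining species declines throughout its range; a
country-override table removes named species from the numerator in
countries where they are known not to be declining. The denominator is
the niche's full richness, including unclassified-trend species — they
are niche members, consistent with the descriptive summaries. Cells are
masked either where the niche richness is ≤ 5 (`mask_mode = "richness"`,
default) or where the number of declining species is ≤ 5
(`mask_mode = "decliners"`). Both readings of the low-richness rule
appear in practice and they differ, so both are first-class; pick one
explicitly when comparing maps. Per-threat layers must not be summed
into a "total declining" layer: species carrying several threats are
counted in each.

Crepuscular layers are producible but left out of the default map set —
crepuscular richness is ≤ 5 over most cells, so nearly everything would
be masked.

## The synthetic generator

`synth_config()` fixes the generative conditions; the defaults emulate
the composition of the terrestrial-mammal study system:

* niche base frequencies (0.695, 0.0225, 0.1045, 0.178) matching the
  observed nocturnal/crepuscular/cathemeral/diurnal mix;
* decline logits: intercept −0.40 (a ~40% baseline decline rate) with
  niche effects (−0.01, +0.12, +0.49) — the effects implied by the
  observed per-niche decline percentages;
* a latent Brownian effect on the logit scale with marginal variance
  0.5 (moderate phylogenetic signal in decline beyond niche);
* threat rates per niche chosen so habitat loss dominates (~0.85–0.91
  among decliners), harvesting rises from nocturnal (0.25) to diurnal
  (0.52), and the five minor threats stay rare;
* missingness: 3% missing niche, 42% unknown downloaded trend (with 75%
  of rule-uncovered species recovered by "literature"), 1.3% unknown
  threats; 2.5% marine and 5% fossorial flags;
* primates concentrated among diurnal species (32.1% of diurnal vs
  3–4% elsewhere), giving the primate/non-primate split something real
  to separate.

Diel niche evolves along a birth–death tree (`ape::rphylo`, rescaled to
unit depth) under a Markov model with rate matrix `Q_ij = r π_j`, whose
stationary distribution is exactly the configured niche mix, with the
root state drawn from it — so tip frequencies match the target at every
rate. The default rate `r = 6` keeps the trait phylogenetically clumped
while making all four niches essentially always present at study sample
sizes; much lower rates frequently produce monomorphic trees, which the
real assemblage is not. The tree ensemble is the base tree with
mean-preserving log-normal branch jitter (SD 0.1), standing in for a
Bayesian posterior sample; ranges are contiguous random blobs on a small
grid; a Voronoi partition provides a toy country raster.

What the generator does *not* emulate: real biogeography (richness
gradients, range-size structure), correlated threat co-occurrence beyond
niche, taxonomic structure beyond the primate flag, and the exact
Ives–Garland binary evolution process — the latent decline effect is a
threshold-style Gaussian on the Brownian covariance, which is the
generator's model, not the estimator's. Passing tests therefore show the
pipeline recovers the right signs and calibrated uncertainty under
study-shaped data, not that any particular real-world coefficient is
reproduced.

## Calibration experiments behind the test bands

The simulation bands frozen into the test suite were fixed by dedicated
pre-build experiments at the stated problem sizes:

* *Type-I error*: 200 replicate datasets of 400 tips with all niche
  effects zero and latent signal 0.5; per-coefficient rejections at
  p < 0.01 must sit inside the central 99.9% binomial band around 0.01.
* *Poisson recovery*: 50 replicates of 400 tips with effects (0.2, 0.3,
  0.5); each niche effect within 2 SEs of truth in ≥ 90% of replicates.
  This experiment generates conditionally independent Poisson counts:
  when a tree-valued latent term is added to the log-mean, it is
  genuinely confounded with the tree-evolved niche, and no marginal
  estimator attains nominal coverage — a limitation of the design, not
  of the estimator, so the clean design is the meaningful oracle.
* *Mk recovery*: the ML rate falls within a factor 2 of truth in 50/50
  replicates at 500 tips; imputation recovers ≥ 80% of masked states
  when the trait is conserved.
* *End-to-end effect recovery*: with a +0.5 diurnal effect at 800
  species and 10 trees, the ensemble mean diurnal coefficient is
  positive in every replicate study, and that sign recovery is the
  frozen regression band. The marginal effect is attenuated below +0.5
  by the latent variance and by unclassified species coded 0, so tier
  attainment is *not* implied at this effect size and is not asserted.

## Problem sizes and numerical choices

The default test-suite scale (hundreds of species, 3–12 trees, 12×12 to
20×20 grids; 400-tip calibration runs) keeps the whole suite to a few
minutes on one CPU while leaving every statistical check meaningfully
powered. Numerical constants: covariance normalised to unit depth (a
pure reparameterisation that stabilises the `a` search); Cholesky with a
1e-8 jitter fallback for near-singular correlations; penalised-score
Newton with step-halving; `a` profile optimised by golden-section to
1e-6. Degenerate inputs (constant responses, single observed Mk state,
empty niches, empty subsets) return flagged results rather than errors
wherever the pipeline can continue.

## Known limitations

* The binary model is a working-correlation approximation in the
  Ives–Garland spirit, not their exact evolutionary process; `a` is a
  signal dial, not an estimate of a switching rate.
* With one phylogeny there is no replication across clusters, so GEE
  standard errors are model-based by necessity.
* The pseudo-R² is computed on the independence likelihood; treat it as
  descriptive, and only compare values computed the same way.
* The category rule imports the Red List's threatened/declining
  association; on data where that concordance is weak,
  `category_trend_concordance()` should be checked before trusting
  rule-assigned trends.
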