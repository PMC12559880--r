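---
title: "Depth-resolved SOC change from land-use change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved SOC change from land-use change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Converting land between cropland, grassland and forest changes the soil's
carbon inputs and disturbance regime, and soil organic carbon (SOC) drifts
toward a new equilibrium over decades to centuries. Because no practical
monitoring design can watch a single site across a century, equilibrium
change must be inferred by comparing *different* sites under different land
uses. `reciproSOC` implements a data-driven reciprocal modelling pipeline
for this inference, resolved over four depth strata (0–10, 10–30, 30–60 and
60–90 cm) plus the forest litter layer:

1. **Group separation.** Sites are split by current land use. Only mineral
   soils at equilibrium with respect to land-use change are kept: organic
   soils (SOC > 10% in any increment, or Histosols) are excluded, as are
   ley-rotation croplands and sites whose histories show a conversion more
   recent than the re-equilibration horizon (151 years for cropland, 79 for
   grassland; forests are treated as at equilibrium).
2. **Counterfactual model.** For a direction A→B, a stacked ensemble —
   random forest, gradient-boosted trees and RBF support-vector regression,
   combined by a simple mean — is trained on the B group to predict the SOC
   stock of a stratum from covariates that land use does not alter
   (texture, coarse fraction, terrain, climate, soil group, parent
   material; pH and C:N only when neither side is forest, since forest
   biota drive both). Training runs under a nested, spatially blocked
   cross-validation: outer 5-fold splits built from 100 km grid blocks,
   repeated (10 repeats at full scale), with an inner block-wise CV driving
   a random hyperparameter search per learner.
3. **Applicability screen.** Before predicting, each A-group site is placed
   in the importance-weighted, standardised predictor space of the training
   group; its dissimilarity index (DI) is the Euclidean distance to the
   nearest training site divided by the mean pairwise training distance.
   Sites whose DI exceeds the 0.95 quantile of the cross-validated training
   DI distribution are excluded as extrapolation.
4. **Stock change.** For each retained site, `delta = predicted − observed`
   is the equilibrium change attributable to conversion. Direction-level
   means carry 95% percentile bootstrap intervals (10,000 replicates at
   full scale). Directions involving forest add a litter stratum:
   conversion to forest predicts a litter stock from a restricted model
   (soil group, climate, elevation, slope) against an implicit zero;
   conversion away from forest removes the observed litter.
5. **Driver model.** Pooling both directions of a pair, the per-site sum of
   absolute mineral-stratum changes is modelled from mechanistic covariates
   with the same ensemble machinery; permutation importance and accumulated
   local effects (ALE) describe what governs the magnitude of change.

## Stocks and depth harmonization

Stock is computed per increment as
`SOC% × fine-soil bulk density × (1 − rock-fragment fraction) × thickness`,
whose units collapse to Mg C ha⁻¹ directly. The two inventory designs
sample different fixed depths (agricultural 0–10/10–30/30–50/50–70/70–100
cm; forest 0–5/5–10/10–30/30–60/60–90 cm plus litter). Harmonization
downscales every profile to 1 cm slices — values constant within an
increment unless an optional per-horizon SOC allocation re-apportions
concentration across a horizon boundary under exact stock conservation —
and re-aggregates to the target strata with the scheme's weights: thickness
weights for bulk density and rock fragments, fine-soil-stock weights
(`bd × (1 − rff)` per slice) for SOC, clay, silt, N and pH. pH is averaged
on pH units. The increments are half-open `[top, bottom)`; litter is a
separate stratum, never an increment; agricultural slices below 90 cm are
discarded. Stock is conserved exactly (tested to 1e−9 relative on
randomized profiles), and for aligned bounds the map is the identity.

A consequence worth making explicit: where source increments straddle a
target boundary (30–50/50–70/70–100 against 30–60/60–90), the
constant-within-increment assumption redistributes mass between the target
strata by a few percent for exponentially decaying profiles. This is a
property of the measurement design, not of the estimator, and both
inventories share it. The synthetic generator therefore records its ground
truth twice — exact 1 cm stocks, and the same profiles rendered through
each inventory's sampling scheme — and recovery is judged against the
scheme-rendered truth, which is the estimand the harmonized data carry.

## The synthetic inventory generator

The generator is first-class, tested code: every downstream stage is
validated against its known counterfactuals. Its defaults emulate the
structure of the German inventories: land-use frequencies 0.45/0.17/0.38,
WRB group frequencies led by Cambisol 39%, Luvisol 13%, Stagnosol 13%
(plus 2% Histosols to exercise the organic filter), precipitation with mean
803 mm on 491–2144 mm (shifted truncated lognormal), temperature 8.9 °C on
4.6–11.3 °C (truncated normal), Dirichlet texture clipped to ≤ 76% clay and
≤ 96% sand, and coarse-fragment means of 6.8%/1.4%/3% for
forest/grassland/cropland. About 15% of agricultural sites are planted to
fail the equilibrium screen.

True SOC concentration is `(A_LU · exp(−k_LU z))^s(wrb) · m(wrb) ·
g(clay) · h(MAP) · ε`, with surface levels and decay rates per land use
(cropland A = 2.2%, k = 0.035 cm⁻¹; grassland 4.0, 0.040; forest 4.8,
0.042), a soil-group level multiplier `m` (Gleysols and Fluvisols highest)
and contrast exponent `s` that together make the WRB group the dominant
driver of change magnitude, a weak clay term, a weak precipitation term,
and site-level lognormal noise (mean 1, SD 0.25). Cropland concentration is
replaced over 0–30 cm by its plow-layer mean. Bulk density rises with depth
and is a site property shared across counterfactual states, as is the rock
fragment fraction, so ground-truth deltas are antisymmetric exactly. Forest
litter is lognormal with location decreasing in the site's true 0–10 cm
mineral stock (inverse relationship; mean 20 Mg C ha⁻¹ at the reference
stock). Observed increments add 5% lognormal measurement noise to the
increment SOC concentration. pH and C:N are site properties independent of
land use within the agricultural contrast — the premise under which they
are admissible predictors — while forest sites are acidified and
litter-widened (forest-involving models exclude both).

What the generator does *not* emulate: spatial autocorrelation of soils and
climate (covariates are drawn independently per site, so spatial blocking
is exercised structurally, not adversarially), non-monotone depth profiles
(a single exponential cannot reproduce sign flips such as a mid-profile
stratum moving against its neighbours), inventory-specific measurement
protocols, and genuinely asymmetric hysteresis between conversion
directions. Passing recovery tests therefore shows the estimator is
consistent under the stated generative assumptions — not that real
inventories satisfy those assumptions.

## Numerical and design choices

* **Hyperparameter spaces** (the sources are silent): forest 500 trees
  (fixed; scaled down in small runs), `mtry ∈ [⌈p/5⌉, p]`, minimum node
  size {1, 5, 10}; boosting 100–2000 rounds, depth 1–6, learning rate
  log-uniform 10⁻³–10⁻⁰·⁵, row subsample 0.5–1; SVR cost log-uniform
  10⁻¹–10³, RBF γ 10⁻⁴–10⁰, ε log-uniform over [0.01, 1]·SD(target).
  ε is sampled on the log scale because a tube wider than the signal
  degenerates to the mean predictor; uniform sampling would waste most
  draws there. Ties in the search break by draw order.
* **Encoding.** Categoricals are strings at I/O, one-hot encoded inside the
  models against training-fold levels; an unseen level at prediction
  encodes to an all-zero block and is logged. Missing numerics take the
  training-fold median. SVR inputs are standardised with training-fold
  statistics.
* **Determinism.** All randomness descends from explicit seeds; fits
  canonicalise their internal row order (by `site_id`) so results are
  invariant to how the caller sorted the table. Identical config + seed
  reproduces result files byte-for-byte.
* **Uncertainty.** Per-site spread is the type-7 IQR of the 10 per-repeat
  predictions; direction-level intervals are percentile bootstrap over
  sites. The reported `±` is the interval half-width; asymmetric bounds are
  stored. The bootstrap resamples *sites*, holding the fitted models fixed:
  model-level error shared across sites is not propagated, a limitation
  discussed below.
* **Applicability.** The DI normalisation (mean pairwise training
  distance), fold-aware nearest neighbours for the training DI, and the
  0.95-quantile threshold follow the published applicability method behind
  the screening step; the Tukey upper-whisker threshold is available as an
  option. Weights are max-normalised permutation importances clipped at
  zero; zero-variance predictors are dropped with a warning.
* **ALE.** 20 quantile bins by default; points sit at their bin's upper
  edge for centring, so every curve's count-weighted mean effect is zero to
  1e−10. Categorical ALE orders categories by within-category mean and
  accumulates adjacent differences. The driver target uses mineral strata
  only; whether litter belongs in the magnitude-of-change target is an open
  modelling question, and excluding it keeps the target's depth span
  well-defined (0–90 cm of mineral soil).
* **Exclusion precedence** for filter reporting is organic → ley →
  equilibrium; the order is a reporting convention, not a scientific claim.
* **Subsoil share.** The share of absolute change attributed to 30–90 cm is
  `|Δ₃₀₋₉₀| / (|Δ₃₀₋₉₀| + |Δ₀₋₃₀|)` on direction means; its interval comes
  from a site-level bootstrap of the ratio. Averaging this ratio across
  directions from published per-stratum means gives ≈ 28%, consistent with
  the ~30% headline figure derived from such tables.

## The scaled-down validation study

`validation_settings()` freezes the design used by the acceptance checks:
1500 synthetic sites, the grassland→cropland direction, 2 repeats of the
spatial 5-fold plan, 2-draw random search over 2 inner folds, 60 trees,
40–100 boosting rounds, SVR cost capped at 10², and 10,000-replicate
bootstrap intervals. Two considerations fixed the direction choice: the
training group should be the largest land-use class (cropland), because the
bootstrap interval only reflects site-resampling noise — whatever
systematic error the counterfactual model carries is shared by all sites
and must be small relative to that interval for coverage to hold — and the
predicted group (~200 grassland sites after filtering) then yields
intervals wide enough to be informative rather than vacuous. Running the
reciprocal direction (training on ~200 grassland sites) at the same scale
shows exactly the anticipated failure mode: a few-percent shrinkage bias,
produced by covariate shift between groups and an undersized training set,
exceeds the narrow interval over ~570 predicted sites. That behaviour is a
faithful miniature of the method's real limitation, which the full-scale
design addresses with larger groups, 10 repeats and a 30-draw search.
Problem sizes throughout the test suite (hundreds of sites, tens of trees)
were chosen so the full validation battery runs on a single CPU in minutes;
they are stated in `validation_settings()` and the tests themselves.

## Known limitations

* Bootstrap intervals condition on the fitted models; model error shared
  across sites (shrinkage under covariate shift, small training groups) is
  not inside them. The applicability screen narrows, but does not remove,
  this gap — importance-weighted distance can under-weight a covariate that
  matters for the shift but explains little training variance.
* The harmonization's constant-within-increment assumption biases strata
  whose bounds cross source-increment bounds for curved profiles; the
  optional horizon-allocation table mitigates it only where horizon data
  exist.
* Counterfactual predictions inherit every "not affected by land use"
  judgement in the predictor specs; if a predictor is in fact altered by
  land use, its contrast leaks into the estimated change (the generator's
  pH/C:N design documents exactly this hazard).
* The pipeline estimates equilibrium-to-equilibrium change; it says nothing
  about trajectories, rates, or non-LUC drivers of SOC drift.
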