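---
title: "Linking farm surveys to soil monitoring: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking farm surveys to soil monitoring: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

farmsoc estimates the effect of agricultural management on soil organic
carbon (SOC) by joining two data worlds that never meet at the plot level:
representative farm surveys, which describe management but hide farm
locations, and systematic soil-monitoring points, which measure SOC but not
management. This vignette explains the model and the choices behind each
stage, including the ones where the design was genuinely open.

```{r setup, eval = FALSE}
library(farmsoc)
```

## The estimation problem

Management at a monitoring point is unobservable; what can be estimated is
the management of the *population of farms that plausibly cultivate that
point*: farms in the same administrative region and altitude class growing
the same crop. The point-level "management indicator" is therefore a
group-level weighted median, and all downstream inference is about how these
group-level management profiles relate to point-level SOC. Two consequences
matter for interpretation:

* predictions shared by all points of a group understate true between-farm
  variability — effects are attenuated relative to plot-level management;
* the anonymity cut-off (at least 15 farms per group, here `min_group_size`,
  default 15) forces a tiered fallback, and tier provenance is recorded per
  point so users can stratify by matching quality.

The farm weight `w = sqrt(area/UAA * area/total_area)` balances a farm's
specialization in the crop against its share of the group's crop area. We
use the *lower* weighted median (smallest value whose cumulative weight
reaches half the total) rather than an interpolating variant: it is exactly
reproducible, minimizes the weighted absolute deviation, and ties resolve
deterministically to the smaller value. The weighted SD uses the
population (frequency-weight) form. Tier 3 matches "geographically closest
farms of the same land-cover class in the same country"; farms carry no
coordinates, so whole region-crop groups are accumulated in order of
great-circle distance between the point and region centroids until the
cut-off is met — the finest resolution the data admit.

## SOC metrics

Stocks use a fixed 0–20 cm depth, `stock = Bd_ref * OC * 20 * 0.1 * (1 -
Cf)`. A true equivalent-soil-mass correction is out of scope (it needs
depth-layered data); instead a *reference* bulk density is predicted for
every point — including those with measured bulk density — so land uses with
systematically different densities are compared on a common mass basis.

The bulk-density model is an exhaustive OLS search per land use over
hierarchy-respecting subsets of {sand, clay, sand×clay, total N, pH, mean
annual precipitation}: 32 main-effect subsets plus 16 with the interaction,
48 candidates, ranked by AIC. OC is structurally excluded — predicted
density multiplies OC in the stock equation, so admitting OC would count it
twice and bias land-use comparisons. Two numerical choices:

* *degenerate fits*: when a candidate's mean squared residual falls below
  1e-20 the Gaussian likelihood diverges and AIC ties at −∞; selection then
  prefers the smallest perfectly fitting model, which is the limit of the
  AIC penalty for equal residual sums of squares and makes noiseless
  simulation recovery deterministic;
* *clipping*: predictions are clipped to 0.1–2.2 g cm⁻³, a generous
  physically plausible range for fine-earth density; clipped counts are
  reported.

Benchmark ratios divide the stock by the zone × land-use typical stock;
missing zone labels are imputed with a random-forest classifier (500 trees,
minimum node size 1, mtry 3) on OC, region, land cover and edaphic/climatic
covariates, with the out-of-bag error reported. Yearly ΔSOC is the
concentration difference between the two survey dates divided by the years
elapsed. Cleaning removes organic soils above 160 g C kg⁻¹ (strictly above;
applied to the dates each metric uses, with counts logged separately),
land-use-inconsistent points (change metric only) and implausible changes —
interpreted as |ΔOC|/OC_t0 > 1 over the whole period, or more than
3 g kg⁻¹ yr⁻¹, strict inequalities throughout.

## Intensity composite and mixed models

The intensity index ranks each indicator across the whole analysis set
(average ranks for ties, descending for extensifying practices: organic
probability, manure shares, crop diversity and richness, ley + fodder
share), min–max scales the ranks to [0, 1], averages constituents within
their function group (nutrient input N/P/K at 1/3 each; manure share N/P/K
at 1/3 each; diversity and richness at 1/2 each; singletons at 1), and
averages the group scores, ignoring missing groups. A constant variable maps
to 0.5 — the midpoint avoids pushing whole groups to an extreme when a
variable is uninformative. Ranking is done jointly across land uses;
arable-only variables simply go missing off-arable. Ley and fodder-legume
shares are combined into one variable before ranking. Whether nutrient input
should enter as one group or three variables is a judgment call; the spec
object (`default_intensity_spec()`) makes the grouping explicit and
swappable.

Management effects are estimated with linear mixed models, random intercept
per pedoclimatic zone: stocks are log(1+y)-transformed, benchmark ratios
log-transformed, ΔSOC asinh-transformed. An `identity` option exists for
simulation studies where effects are generated on the response scale. N
input enters with linear plus quadratic terms (divided by 100 so both are on
comparable scales) to allow the hump-shaped grassland response; elimination
can drop the quadratic. Backward elimination iteratively removes the least
significant droppable term above alpha = 0.05 (the conventional level),
respecting marginality via `drop1` scopes; the final model is compared to
the random-intercept-only null with a maximum-likelihood likelihood-ratio
test. Marginal effects hold the non-focal covariates at their observed
distribution (counterfactual averaging), set the random intercept to zero
and back-transform naively — no smearing correction, so back-transformed
means are conditional medians under log-normal errors; this is flagged
rather than corrected because the transformations are monotone and the
curves are used for ordering and display.

## Scenarios

Per zone × land-use stratum, points are ordered by the management part of
the fixed-effect predictor (zone intercepts excluded; ties broken by point
id), and the management effect is the mean observed stock of the top
`ceiling(0.1 n)` points minus the bottom `ceiling(0.1 n)`, requiring at
least 20 points. The option space multiplies stratum effects by stratum
areas. The scenario baseline is the *stratum mean* stock — the best scenario
is `(top decile mean − stratum mean) × area` — rather than the opposite
decile, so gains and losses need not be symmetric; a `baseline = "decile"`
flag gives the symmetric variant. Decile-mean SEs are combined assuming
independence (the deciles are disjoint subsamples; the shared-mean
covariance is ignored, slightly overstating uncertainty), and the SE of a
total is the square root of the sum of squared area-weighted component SEs.

## The synthetic world

The generator emulates the structure of the real data sources: a farm-survey
table (region, altitude class, farm type, size class, UAA, organic flag,
livestock, mineral N/P/K, per-crop areas), a tillage-area table by region ×
size × type, a soil-point table with two-date OC, optional measured bulk
density and edaphic covariates, and a zone × land-use benchmark table.
Distributions the sources do not publish were chosen once for survey
realism: crop areas Dirichlet over the farm's crop set, livestock and
fertilizer rates log-normal (positive, right-skewed), organic flags
Bernoulli with region-specific probability. The within-group management
spread is a free parameter (`fert_sdlog`, `livestock_sdlog`) because real
surveys do not report it. Defaults: 4 regions × 300 farms, 1200 points,
zone baselines 80/60/50/35 Mg C ha⁻¹, stock noise SD 8 Mg C ha⁻¹, OC
measurement SD 0.5 g kg⁻¹, bulk-density noise SD 0.05 g cm⁻³, a third of
points with measured bulk density, 19 % masked zones, survey dates 2009 and
2018.

The ground-truth management of a point is defined as the tier-matched
weighted-median prediction computed from the generated farms, and the
expected stock is exactly `zone baseline + Σ slope × indicator` (default
slopes: manure N share 25, ley share 30, organic probability 10 Mg C ha⁻¹
per unit). The later-date OC is back-computed through the stock equation
from the generated bulk density, so a noiseless configuration is recovered
*exactly* by the pipeline — the basis of the end-to-end consistency tests.
Points carry a single region id usable as both a coarse and fine
administrative key, and one country.

What the generator does *not* emulate: spatial autocorrelation of soils,
farm-to-plot geolocation error, non-random survey non-response, and
correlated measurement errors between survey dates. Passing tests therefore
demonstrate that the estimators do what they claim under a known
data-generating process — not that the real-data estimates are unbiased.

## Problem sizes and verification

The test suite verifies, among others: the weighted median against a
brute-force weighted-absolute-deviation minimizer on every seeded vector up
to length 8; recovery of the generative bulk-density model {pH, total N,
sand×clay} with coefficients to 1e-6 from noiseless data; slope recovery for
the manure-share and ley-share effects within their 95 % CIs in at least 90
of 100 replicates at 5000 points each; likelihood-ratio type-I error within
two Monte-Carlo SEs of 0.05 over 500 null replicates (2 regions × 100
farms, 200 points per replicate — sizes chosen so the whole simulation
battery completes in a few minutes on one core); and exact (1e-6)
ground-truth stock recovery plus correctly ordered scenario deltas on a
noiseless 800-point world.

## Known limitations

* Group-level management predictions attenuate effect estimates; the
  package reports matching tiers but no measurement-error correction.
* The scenario totals are steady-state contrasts — no transient dynamics,
  no adoption timelines, no climate interaction.
* Decile SEs ignore the covariance with the stratum mean.
* The bulk-density search is restricted to the six named terms; richer
  pedotransfer functions exist but would change the mass-standardization
  contract.
* Tillage intensity is joined from cell-level aggregates and is missing for
  farms without a matching cell, so its effects are estimated with less
  resolution than the other indicators.
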