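---
title: "A biophysical typology of mangrove coastlines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biophysical typology of mangrove coastlines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mangrovetyper)
```

## The problem and the model

Mangrove extent maps are binary. The ecological questions that matter —
where sediment comes from, how vulnerable a forest is to sea-level rise,
which restoration technique can work — depend on landform. This package
classifies a coastline's mangroves into four macroscale geomorphic types
(deltaic, estuarine, lagoonal, open coast) and two sedimentary settings
(terrigenous, carbonate), then quantifies extent change and above-ground
biomass (AGB) by type.

The classification unit is the **coastal embayment polygon (CEP)**: an
indent in the coastline. We define indents constructively by
morphological closing — dilate the land by a disc of radius $r$, erode by
the same disc, and take the water that became land. A disc of radius $r$
cannot enter a concavity narrower than $2r$, so funnels, channel
networks and choked lagoons seal while straight or convex coast is a
fixed point. The closing is computed on a raster (exact Euclidean
distance transforms, Felzenszwalb–Huttenlocher algorithm in compiled
code); CEPs are the 4-connected components of the sealed water at the
working resolution. A channel narrower than a cell cannot connect two
indents, which is exactly the "Euclidean allocation splits them"
behaviour wanted at sub-resolution scale; a contiguous multi-mouth
channel network (a delta's distributaries) stays one CEP, so the delta
rule below can see all its outlets.

### Working frame

All geometry lives in a planar equal-area frame in kilometres, so areas
are exact cell counts × cell area; a real-data application must
reproject to an equal-area CRS before any area computation. The raster
convention is upper-left origin, half-open square cells, nearest-cell
(no interpolation) point sampling — "value nearest to the location"
semantics for training sites. Defaults: 0.5 km cells, closing radius
$r = 10$ km, minimum CEP area 1 km², CEP filter at 30 km² landmass and
20 km to mangrove.

## Geomorphic classification

**Deltas first, by rule.** A CEP with more than two river outlets to the
ocean is a delta candidate (an outlet is the terminal vertex of a
flowline with no downstream pointer, snapped to the CEP within 1 km —
closing leaves a small unsealed lens at each channel mouth, hence the
snap). Candidates pass through the review hook; a config-supplied list
of known deltas can be unioned in, standing in for the literature
route. Delta CEPs leave the forest pool, and delta extents may merge
several mouth CEPs into one unit.

**Then a two-pass random forest.** Ten covariates per CEP:

| variable | meaning | targets |
|---|---|---|
| v1 area, v2 perimeter | size | — |
| v3 compactness $4\pi A/P^2$ | shape roundness | bays high |
| v4 mouth width | opening to sea | lagoons tiny |
| v5 elongation (min-area-rectangle length/width) | funnel shape | estuaries |
| v6 closure ratio (mouth / max interior width) | chokedness | lagoons ≪ 1 |
| v7 catchment area, v8 flowline count | river dominance | estuaries ≥ 1 |
| v9 routed annual precipitation, v10 seasonality | freshwater input | estuaries |

The exact published variable set lives in supplementary material not
reproduced in the main text; this set is a declared default spanning the
three stated families (shape, catchment, precipitation) and is
replaceable via the covariate table contract. Catchments aggregate the
whole watershed polygons of every flowline touching the CEP plus their
upstream closure over downstream pointers; "precipitation moving through
the network" is implemented as catchment-masked monthly means (true
flow-accumulation routing is out of scope).

The forest is an in-package bagged CART (Gini, `mtry = floor(sqrt(p))`,
trees grown to purity, majority vote) because no random-forest package
is available in the target environment; these are the standard
classification defaults, and the implementation name and settings are
recorded on every run object. The published workflow used 100,000 and
75,000 trees on 1,171 training CEPs; tree count is a logged knob, and
tests run at ≤ 500 trees — at tens of covariate rows the vote
distribution is indistinguishable, while the contract (composition
800/71/300 accepted, 20% holdout, per-class recall reported) is
unchanged. Exact vote ties break bay > estuary > lagoon, bays being the
modal training class. The second pass retrains on the original training
rows plus reviewed labels, re-predicts the unreviewed bay-labelled pool,
and flags two-pass disagreements for review; every CEP ends with a label
and a provenance tag (`pass1` agreement / `pass2` / `review`).

**The review hook** mechanises visual inspection: it returns the truth
label flipped to a random different class with probability
`error_rate`. With a perfect hook the reviewed set is exactly corrected,
as in the published procedure; with a fallible hook the correction is
only worth applying when the model is weaker than the reviewer, which
the tests exercise both ways.

## Patch attribution

Patches are 8-connected components of the maximal (union) extent. Three
steps, mirroring the three stated aims: (1) any patch touching two or
more CEPs is split along the Euclidean allocation boundary between the
competitors, conserving area exactly (cells are partitioned); (2)
patches touching one CEP inherit its type, with bay ⇒ open coast; (3)
orphans go to the nearest CEP whose catchment contains them, else the
nearest CEP within 20 km, else open coast without a CEP. Distance ties
prefer a catchment-sharing CEP, then the lower CEP id. Same-type patches
sharing a CEP (or a delta unit) merge into one typological unit; regions
attach by majority area overlap with a config-supplied region layer.
"Very large" single-CEP patches are not split — the published criterion
is unstated — and a warning threshold (7,000 km², just above the largest
published unit) flags suspects.

## Sedimentary setting

Riverine (deltaic/estuarine) settings are terrigenous by definition.
For the rest, a binomial GLM with logit link models P(terrigenous) from
M2 tidal amplitude (m) and mean inorganic suspended particulate matter
(g m⁻³), fitted to non-riverine training sites; both predictors are
always retained regardless of significance. We code terrigenous = 1 so
tidal amplitude carries a positive coefficient — high tidal energy
imports minerogenic sediment — consistent with the reported large
positive tide effect; the source never states its coding. The deviance
pseudo-R² is $(D_0 - D)/D_0$. Units classify at the representative point
(unit cell nearest the centroid) with an inclusive 0.5 threshold — a tie
goes to terrigenous, the majority class — and unsampled units are
flagged terrigenous with a warning. Complete separation is flagged and
coefficients are capped at |50| rather than failing.

## Extent change and AGB

Areas tabulate long-form by region × type (× sediment) × timestep.
Percentages print to one decimal with half-away-from-zero rounding (the
printing convention of the source tables; R's `round` is half-even), raw
doubles ride along as an attribute. Ranked losses order by
$A(t_0)-A(t_1)$ with id tie-breaks.

The AGB model is $\sqrt{\text{mean AGB}} \sim \text{type}$ by maximum
likelihood GLS with a per-type residual variance (`nlme::varIdent`) —
the square-root transform and variance structure address the
non-normality and heteroscedasticity of unit means. The type effect is
the Wald F of the $k-1$ contrasts with $(k-1, N-k)$ df; the Nagelkerke
pseudo-R²
$[1-(L_0/L_1)^{2/n}]/[1-L_0^{2/n}]$ compares against the intercept-only
model with the same variance structure and requires ML (REML likelihoods
are not comparable across mean structures; enforced). Post-hoc pairwise
contrasts of the estimated marginal means on the transformed scale use
the studentized range (Tukey family; Bonferroni and none available — the
source names the marginal-means framework but not its adjustment), and a
compact letter display is built from maximal cliques of the
not-distinguishable graph.

## The synthetic world

`generate_scene()` plants a stated world, not a tunable one:

* **Geometry.** A straight macro-coast with 3 embayments per class at
  24 km spacing (classes shuffled, deltas never adjacent — two abutting
  fans enclose a genuine valley embayment that would read as a spurious
  CEP). Bays are semicircular bites (radius 4–7 km); estuaries funnel
  from 6–10 km mouths over 10–16 km with one trunk river and 1–2 chained
  upstream watershed rectangles; lagoons are 8–14 × 1.5–2.5 km basins
  behind a 1.5 km barrier with a 0.9 km inlet; deltas are Gaussian fans
  (height 6–8 km, σ = height so the flank closing pockets stay below the
  1 km² CEP floor) dissected by a trunk and 4 distributary channels of
  1.4 km width, each with an outlet where its centreline crosses the fan
  edge. These ranges are design choices — the source publishes no
  geometry statistics for its classes — set once from the behaviour of
  the closing operator and documented here, not calibrated to data.
* **Mangroves and loss.** A 1.5 km land fringe around each embayment
  plus open-coast strips; per-type whole-period loss rates default to
  the published 1996–2016 changes (4.3 / 3.1 / 6.9 / 4.3 %), applied by
  removing `round(rate × n_cells)` cells per unit in a fixed random
  order, cumulative across timesteps in proportion to elapsed years —
  extents are nested and per-unit loss is exact to the cell.
* **Environment.** Tide rises west→east (0.4 → 3.2 m, logistic in x),
  SPM is a smooth positive 12-band stack, precipitation has uniform
  seasonality 1.8. Sediment truth draws Bernoulli from
  `plogis(β·(1, tide, SPM))` at unit centroids with β = (−6, 3.0, 0.08):
  strongly separated, so carbonate sits in the low-tide west. 70
  riverine + 82 non-riverine training sites sit on mangrove cells
  (hence within 10 km of the extent), matching the published 152/70/82
  composition.
* **AGB.** The generator draws on the model's own scale:
  $\sqrt{AGB} \sim N(\sqrt{m_t},\ sd_t/(2\sqrt{m_t}))$, the delta-method
  parameterization that reproduces the published data-scale means and
  SDs (117.3/126.3/73.5/111.5 ± 73.6/76.3/59.8/73.7 Mg ha⁻¹). A raw-scale
  Gaussian generator at these CVs would put a ~17% Jensen bias between
  planted and back-transformed fitted means, contradicting the 5%
  recovery the design asks for; under sqrt-scale generation the
  back-transformed estimate is unbiased to O(SE²).

**What a green test does and does not establish.** The world is
well-separated by construction: classes differ cleanly in closure ratio
and river presence, sediment classes in tide. Green recovery tests
establish that the operators are implemented correctly (delineation
finds what closing seals, the forest learns a learnable signal, the GLM
recovers its own generating coefficients, bookkeeping conserves area) —
not that the typology would reach any particular accuracy on real
coastlines, where class boundaries are gradational, coastline sources
disagree, and training labels are expert judgement. Real-data
performance claims are out of scope; the published global figures that
depend on proprietary-scale inputs (12,301 CEPs, global F statistics)
are not reproduced here, only their printed arithmetic.

## Numerical choices and edge cases

* Distance transforms are exact Euclidean on cell centres; erosion uses
  strict `>` r against complement centres so a straight coast is a
  closing fixed point at any radius.
* Raster shape metrics carry staircase bias (a rasterized circle's
  compactness is ≈ 0.62, not 1); they are self-consistent across a
  scene, which is all a classifier needs. Closed-form checks use exact
  polygon CEPs.
* The printed-table fixtures: two rows of the 2016 regional table are
  ambiguous in extraction (digits run together); they were resolved
  against the printed column totals, and the residual ±1–2 km²
  disagreement between summed columns and printed totals is print
  rounding, tolerated explicitly in tests. Row sums for the two
  super-regions used in acceptance are exact.
* Percent printing is half-away-from-zero at one decimal; `-4.2798`
  prints `-4.3`.
* Degenerate inputs: zero-embayment worlds, empty layers, all-nodata
  rasters (an error, never silently 0), zero-variance AGB (error),
  single-class sediment labels (error), complete separation (flag +
  cap), empty corrections (warning, second pass degenerates to a
  retrain).

## Known limitations

Raster-backed geometry means CEP boundaries are staircases and mouth
widths are chord estimates; flow routing is catchment-mask averaging,
not accumulation; the braided-split downstream pointer keeps a single
canonical edge; region layers and known-delta lists must be supplied.
The review hook models reviewer error as independent symmetric flips,
which is optimistic about systematic expert bias.
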