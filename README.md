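# mangrovetyper

Mangrove forests differ radically by landform: river-dominated deltas,
funnel-shaped estuaries, barrier-enclosed lagoons and open coasts deliver
different sediment regimes, support different biomass, and call for
different restoration tactics — yet global mangrove maps are binary
presence/absence layers with no landform context. `mangrovetyper`
implements a biophysical typology pipeline for coastal scientists and
conservation analysts that turns a coastline, a river network and a stack
of environmental rasters into typed mangrove units, and then runs the two
downstream analyses such a typology enables: extent-change accounting by
type, and a variance-structured comparison of above-ground biomass (AGB)
between types.

The pipeline, end to end:

1. **Embayment delineation** — the coastline is generalized by
   morphological closing with a disc of radius *r* (default 10 km); the
   sealed water (generalized minus actual land) splits into coastal
   embayment polygons (CEPs), "indents in the coastline", filtered to
   landmasses ≥ 30 km² within 20 km of the mangrove maximal extent.
2. **Geomorphic classification** — deltas are flagged by the drainage
   rule (more than two river outlets to the ocean, plus an optional known
   list); the rest are classified bay / estuary / lagoon by a bagged CART
   random forest on ten covariates: six polygon-shape metrics (area,
   perimeter, compactness 4πA/P², mouth width, elongation, closure ratio)
   and four catchment/precipitation variables (aggregated upstream
   watershed area, flowline count, network-routed annual precipitation
   and its seasonality). A second forest pass retrains on reviewed
   labels and flags disagreements — the published two-pass workflow with
   the human visual check replaced by a mechanised review hook.
3. **Patch attribution** — mangrove patches are split along Euclidean
   allocation boundaries so each touches one CEP, assigned directly where
   they intersect a CEP (bays ⇒ open coast), and otherwise routed through
   catchment membership and distance fallbacks into typological units
   with per-timestep areas and regions.
4. **Sedimentary setting** — a binomial GLM (logit link) of terrigenous
   vs carbonate on M2 tidal amplitude and mean inorganic suspended
   particulate matter, fitted to non-riverine training sites, classifies
   lagoonal and open-coast units; deltaic and estuarine units are
   terrigenous by definition. Deviance pseudo-R² = (D₀ − D)/D₀.
5. **Change and AGB analyses** — long-format area tables by region ×
   type × timestep with shares and percent changes, loss rankings; and a
   generalized least squares fit of √(mean AGB) ~ type with a per-type
   variance structure (`nlme::varIdent`), Wald F with df (k−1, N−k),
   Nagelkerke pseudo-R², and Tukey-adjusted pairwise contrasts with a
   compact letter display.

Everything is exercisable offline on a **synthetic coastal world** with
known ground truth (`generate_scene()`): planted fans with distributary
channels, funnel estuaries with trunk rivers, choked lagoons, open bays,
mangrove fringes eroded through four timesteps at planted per-type rates,
and smooth tide/SPM/precipitation/AGB fields.

## Worked example

```r
library(mangrovetyper)

res <- run_pipeline(scene_config(), seed = 1, n_trees = 300)

res$units$table[1:3, c("type", "region", "sediment", "area_1996", "area_2016")]
#>      type region    sediment area_1996 area_2016
#> 1 deltaic   west terrigenous     41.00     39.25
#> 2 deltaic   west terrigenous     46.25     44.25
#> 3 deltaic   east terrigenous     38.75     37.00

res$type_changes          # percent change 1996 -> 2016 by type
#>    deltaic  estuarine   lagoonal open_coast
#>       -4.4       -3.1       -6.7       -4.4
```

The planted loss rates were 4.3 / 3.1 / 6.9 / 4.3 % — each recovered to
within one raster cell per unit (lagoonal drifts to −6.7 because the
per-unit removals are whole cells). The AGB analysis at the published
per-type means and SDs (n = 400 per type):

```r
m <- fit_agb_gls(simulate_agb_units(
  c(deltaic = 400, estuarine = 400, lagoonal = 400, open_coast = 400),
  seed = 1))
m
#> <agb_model> sqrt(mean AGB) ~ type, varIdent by type (ML)
#>   F(3, 1596) = 46.83, p = 5.31e-29
#>   back-transformed means: deltaic=120.1, estuarine=121,
#>   lagoonal=71.5, open_coast=113.9
posthoc_contrasts(m)$letters
#>    deltaic  estuarine   lagoonal open_coast
#>        "b"        "b"        "a"        "b"
```

Lagoonal biomass separates from every other type (letter `a`), the
qualitative result the typology is meant to expose.

## Command line

```sh
mangrove-typer simulate --config cfg.json --seed 1 --out out/
mangrove-typer run-all  --seed 1 --out out/
```

Stages: `simulate | build-ceps | covariates | classify | assign |
sediment | change | agb | run-all`; exit code 0 on success, 2 on
validation failure; stage timings on stderr. The script installs under
`exec/` in the package directory.
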