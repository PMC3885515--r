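# fencescape

Barbed- and woven-wire fences are among the densest anthropogenic barriers on
western North American rangelands, impeding daily and seasonal movements of
pronghorn and other grassland wildlife — yet no regional GIS layer of fence
locations exists. **fencescape** builds one by prediction: it implements a
rule-based model that infers fence locations and fence density from three
public data themes — cadastral land-tenure parcels, a classed road network,
and land cover — together with the field-survey design and buffered-point
accuracy assessment used to validate such a model. Everything runs on a fully
synthetic checkerboard landscape generator, so the complete
pipeline is testable with no external data.

It is intended for spatial ecologists and wildlife managers who need a
defensible, reproducible fence layer (and its accuracy) for movement and
habitat-selection modeling.

## The model

Fences are predicted from three sources and merged:

* **Land tenure.** Historic ranches in the region are organized in Public
  Land Survey System *sections* (2.59 km²), the model's base area unit. A
  ledger of cadastral rules turns raw parcels into *fencing units*: BLM land
  is replaced by its grazing-pasture polygons (pasture outlines are the only
  BLM fences); adjacent state parcels are fenced together, as are Bureau of
  Reclamation and Fish & Wildlife Service parcels; state inholdings
  surrounded by BLM dissolve into it; private/tribal parcels merge by common
  owner (below ½ section, also by shared mailing address), units larger than
  two sections (5.2 km²) stand alone and smaller ones dissolve into the
  neighbor closest to 5.2 km²; National Park Service and Forest Service land
  carries no fencing. The surviving unit outlines are the tenure fences —
  a shared boundary is emitted once (one fence between two parcels).
* **Roads.** Primary and secondary roads carry fencing on both sides,
  modeled as the boundary of a square-ended buffer of half-width 19 m
  (primary) / 11 m (secondary) whose end caps — segments of exactly
  2 × half-width (38 m / 22 m) — are deleted so fences never bisect roads.
  Local roads ≥ 1,200 m are assumed fenced; shorter locals become fenced by
  iteratively selecting those touching already-fenced locals (leaving out
  driveways and two-tracks), and carry fencing on one side only.
* **Land cover.** Small (≤ ½ section = 1.3 km²) non-crop inclusions dissolve
  into large croplands (≥ 3 sections = 7.8 km²); a fence always separates
  large cropland from native prairie larger than ½ section; inside large
  croplands all tenure fencing is removed.

At synthesis, fencing inside water bodies and on the study-area boundary is
erased and road fencing lying completely within 20 m of other fencing is
suppressed. Density is the classic line-density estimate — fence length in a
10,000 m circular search window over the window area, on a 1,500 m cell grid,
in km/km².

Accuracy is assessed with 3.2 km roadside transects (≥ 3.5 km apart,
stratified by {Grass, Agriculture, Shrub, Mix} × {Paved, Unpaved}) and
GPS fence events within 200 m of the road, matched under a 30 m
positional-error buffer. Three confusion matrices (roads-only, internal-only,
total) are summarized by Cohen's kappa,
κ = (p₀ − pₑ)/(1 − pₑ), with the large-sample standard error and a normal
95% interval.

## Environment and installation

Geometry overlays (polygon dissolve/overlay, flat-cap buffering) and GeoTIFF
serialization are delegated to a small bundled Python helper: a `python` (or
`python3`) with `shapely ≥ 2.0`, `numpy` and `tifffile` must be on the PATH.
Everything else is base R + `jsonlite`.

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "fencescape", load_package = "installed")'
```

Vector I/O is GeoJSON (projected, meter-unit CRS required; geographic CRSs
are rejected). Shapefile/GeoPackage paths raise a named error — no GDAL
driver exists in this installation.

## Worked example

A 10 × 10-section synthetic world, the full model, its density surface, a
simulated survey and the three assessments:

```r
library(fencescape)
cfg <- fence_config()
ext <- section_extent(10, 10, config = cfg)

tenure  <- generate_tenure(ext, seed = 42, config = cfg)
roads   <- generate_roads(ext, seed = 42, config = cfg)
landcov <- generate_landcover(ext, seed = 42, config = cfg)

truth <- ground_truth_fences(tenure, roads, landcov, cfg, seed = 42)
model <- attr(truth, "model")
print(model$fences)
grid <- fence_density(model$fences, model$study_area, cfg)
print(grid)

frame <- stratify_frame(landcov, roads, cfg)
tr <- generate_transects(frame, 5, cfg, seed = 42)
sv <- simulate_survey(truth, tr, seed = 42, config = cfg)
assessment_report(sv, model, cfg, seed = 42)
```

Output (abridged):

```
[fencescape] tenure fences: 120 parcels -> 63 units, 290.49 km of outline
[fencescape] tenure fencing removed inside large crop: 31.38 km
[fencescape] road fences: 258.97 km from 36 roads
[fencescape] suppressed 2 road fence feature(s) (19.27 km) parallel to other fencing
[fencescape] synthesized fence layer: 476.28 km total
<fence_layer: 146 features, crs EPSG:32100>
<density_grid: 11 x 11 cells of 1500 m, origin (0, 0)>
  km/km^2: mean 1.031, max 1.507 (0 nodata cells)

roads     tp=1155 fp= 0 fn= 0 tn= 38  accuracy=1.00  kappa=1.00
internal  tp= 28 fp= 0 fn= 0 tn= 28  accuracy=1.00  kappa=1.00
total     tp= 28 fp= 0 fn= 0 tn= 28  accuracy=1.00  kappa=1.00
```

The 120 raw parcels merge into 63 fencing units; 31 km of tenure fencing
falls inside large croplands and is removed; 19 km of road fencing is
suppressed as parallel to parcel fencing. Because the simulated ground truth
here *is* the model output (zero perturbation), all three assessments recover
κ = 1 — the survey/assessment machinery is exact. Adding vertex jitter or
feature drop to the truth (`perturb_fences()`) degrades κ in a controlled
way, which is how the recovery tests work.

## Command line

An installed `cli/fencescape` Rscript exposes subcommands
`simulate`, `tenure`, `roads`, `landcover`, `synthesize`, `density`,
`transects`, `assess`:

```sh
Rscript -e 'fencescape::fence_cli(c("simulate", "--sections", "10", "--seed", "1", "--out", "world"))'
Rscript -e 'fencescape::fence_cli(c("density", "--fences", "world/truth_fences.geojson",
                                    "--study_area", "world/study_area.geojson", "--out", "world"))'
```

which writes GeoJSON layers, a GeoTIFF density raster and a zonal-statistics
CSV.

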