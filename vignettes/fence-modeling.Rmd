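---
title: "Rule-based fence modeling: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based fence modeling: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wire fences fragment rangeland landscapes and impede wildlife movement, but
no regional fence maps exist: fences are too small to remote-sense and too
numerous to survey. fencescape predicts them from data that *are* public —
cadastral parcels, classed roads, land cover — under a ledger of rules about
where landowners actually build fences, and quantifies how believable the
prediction is with a roadside survey design and chance-corrected agreement
statistics. This vignette records the model, every tunable that matters, what
the synthetic landscape does and does not emulate, and the design decisions
taken where the method was genuinely open.

## The model and its assumptions

The prediction is the union of three sources, in a fixed order of
construction.

**Land tenure.** The base areal unit is the Public Land Survey System
section, 2.59 km²; parcels are assumed fenced along the outlines of *fencing
units*, produced by an ordered, individually disableable rule ledger
(`tenure_rule_ledger()`):

1. BLM land is removed and replaced by BLM grazing-pasture polygons clipped
   to the BLM footprint; the pasture outline is assumed to be all the fencing
   on BLM land.
2. Adjacent state parcels are fenced together (their shared boundaries
   vanish); the same rule is applied to Bureau of Reclamation and then Fish &
   Wildlife Service parcels.
3. A state parcel *entirely* surrounded by BLM is assumed leased to the BLM
   and dissolves into it. "Entirely" is total boundary coverage: a single
   non-BLM edge keeps the parcel.
4. Private and tribal parcels merge by identical owner at any size; private
   parcels below half a section (1.3 km²) also merge by identical mailing
   address (null addresses never match). Merged units above two sections
   (5.2 km²) stand alone; each smaller unit dissolves into the adjacent
   private/tribal unit whose area is closest to 5.2 km², ties broken by
   longest shared boundary then lowest feature id; isolated islands stay as
   their own unit. The 5.2 km² host criterion operationalizes the stated
   "neighboring parcel of similar size (5.2 km²)", which names an anchor
   without an algorithm.
5. National Park Service and Forest Service land is unfenced. The parcels are
   *flagged* rather than deleted, so landscape area is conserved and their
   boundaries against fenced neighbors survive through the neighbor's
   outline.

Adjacency always means a shared boundary of positive length; corner-touching
parcels are not adjacent (a point contact cannot remove a fence segment).
Outlines are extracted as the set-theoretic union of boundary line-work, so
the fence between two parcels is emitted exactly once.

**Roads.** Primary and secondary roads are assumed fenced on both sides at
half the road-corridor width: 19 m and 11 m respectively. The construction is
a square-ended (flat-cap) buffer, dissolved, converted to boundary lines
split at vertices; segments whose length equals the cap length — exactly
2 × half-width, 38 m and 22 m — are deleted within a 0.01 m tolerance,
leaving offset lines that never bisect the road. Local roads at least
1,200 m long are assumed fenced; shorter local roads become fenced when they
touch a fenced local road, iterated to a fixpoint (endpoint touches count:
driveways touch at their stubs). This filters two-tracks, driveways, and
digitizing slivers out of the fence layer. Fenced local roads carry fencing
on one side only.

**Land cover.** Crop polygons are dissolved; non-crop inclusions at most half
a section that intersect a crop body of at least three sections (7.8 km²)
dissolve into it; residual holes are filled; native prairie larger than half
a section is erased from the large croplands and the resulting boundaries are
fences. All tenure fencing strictly inside large croplands is removed
(portions on the crop boundary are kept: the boundary *is* the modeled
fence).

**Synthesis.** Modeled fencing inside an exclusion area with provided fence
data is dropped; fencing inside lakes/rivers and segments lying on the
study-area boundary is erased; road fencing completely within 20 m of
tenure/land-cover fencing is suppressed (no parcel fence parallel to a nearby
road fence); provided fences are appended unmodified.

**Density.** Line density with a flat circular kernel: total fence length in
the 10,000 m search circle around each 1,500 m cell center, divided by the
circle's area, in km/km². The grid origin snaps to the study-area
bounding-box corner for determinism; cells with centers outside the study
area are nodata. Zonal means and maxima are taken over cell centers.

## Accuracy assessment

Transects are 3.2 km stretches of road, traced 1.6 km both ways from random
midpoints at least 3.5 km apart, drawn length-weighted within the eight
{Grass, Agriculture, Shrub, Mix} × {Paved, Unpaved} strata. A fence belongs to
the roadside when it lies within 200 m of the road; fence-structure changes
shorter than 100 m are not recorded.

Three assessments share a 30 m positional-error buffer:

* *Roads*: transect lines densified to points every 30 m; a point within
  30 m of the modeled **road** fencing is a model positive. Positives come
  from field-fenced transects, negatives from non-fenced ones.
* *Internal*: the model minus road fencing is reduced to its intersection
  nodes; a survey GPS point matches a node when their 30 m disks overlap
  (center distance ≤ 60 m). Negatives are random points on fenced transects
  away from survey points.
* *Total*: GPS points against all modeled fencing, both buffered
  (center-to-line distance ≤ 60 m); negatives are random points along
  non-fenced transects.

Each table is summarized by Cohen's kappa — observed accuracy minus chance
agreement over one minus chance agreement — with the Fleiss–Cohen–Everitt
large-sample standard error and a normal 95% interval. The package's
implementation reproduces an independent reference implementation
(statsmodels) to twelve decimals on frozen tables.

## Parameters that matter

All thresholds live in one `fence_config()` object (meters and km²):

| parameter | default | meaning |
|---|---|---|
| `section_area_km2` | 2.59 | PLSS section, base areal unit |
| `half_section_area_km2` | 1.3 | mailing-address merge / inclusion absorption threshold |
| `two_sections_area_km2` | 5.2 | fencing-unit retention threshold |
| `three_sections_area_km2` | 7.8 | large-cropland threshold |
| `primary/secondary/local_halfwidth_m` | 19 / 11 / 11 | road buffer half-widths |
| `*_cap_len_m` | 38 / 22 / 22 | cap segment lengths, forced = 2 × half-width |
| `long_local_min_len_m` | 1,200 | fenced local-road seed length |
| `parallel_suppress_dist_m` | 20 | road-fence suppression buffer |
| `density_search_radius_m` / `density_cell_size_m` | 10,000 / 1,500 | density kernel |
| `accuracy_buffer_m` | 30 | positional-error buffer |
| `transect_length_m` / `transect_min_spacing_m` | 3,200 / 3,500 | survey design |
| `roadside_max_dist_m` | 200 | roadside membership |
| `min_structure_change_len_m` | 100 | event merge distance |
| `length_tolerance_m` | 0.01 | all "exactly N m" comparisons |

Package-specific tunables: `densify_interval_m` (30 m; the transect-to-point
conversion interval, which the source method leaves data-driven),
`local_fence_side` (`left` of digitized direction by default — determinism —
with `right` and seeded `random` alternatives), `hole_fill_cell_m` (30 m,
the nominal raster cell of the hole-filling step; see below),
`negative_exclusion_m` (60 m; see below), `prairie_classes`
(grassland/shrubland/mixed — the method names no explicit prairie class
list), and `transect_min_road_len_m` (800 m: field crews do not lay 3.2 km
transects on driveways).

## Numerical choices and degenerate inputs

* **Exact-length cap deletion** is robust because flat caps with mitre joins
  produce the cap as a single straight boundary segment; the test is
  `|len − cap| ≤ 0.01 m` after splitting boundaries at every vertex. A
  genuine fence segment of exactly cap length would also be deleted — that
  is the model's stated rule, not an accident.
* **Cross-class dissolve.** Buffers are dissolved across road classes before
  boundary extraction (the stated rule dissolves per class): otherwise the
  fences of one class bisect crossing roads of another class and the
  "no fence crosses a centerline" invariant is false on mixed networks. Cap
  matching still uses each class's cap length.
* **One-sided local fences** use the offset-curve construction, the exact
  closed form of buffer → boundary → erase-one-side → remove caps for the
  surviving side.
* **Hole filling** is implemented exactly in vector space (interior rings
  removed) rather than by a raster round-trip; the raster pass in the
  original workflow exists because the GIS used had no direct hole-fill and
  it costs one cell of discretization error. The configured cell size is
  kept as a sanity bound — a cell larger than the smallest polygon is an
  error naming that polygon.
* **Suppression containment is strict**: a road fence at exactly 20 m from
  other fencing lies on the buffer boundary, is not *within* it, and is
  retained — deterministically.
* **Zero-length roads** are skipped with a warning; empty layers flow
  through every operation and produce empty outputs rather than errors,
  except where a statistic would be undefined (empty transect classes, empty
  confusion tables), which raise.
* **Kappa degeneracy**: chance agreement of 1 (all mass in one margin) is a
  defined error, not a division by zero.

## The synthetic landscape: what it emulates, what it does not

`generate_tenure()` tiles the extent into exact square sections with a
checkerboard of agencies (defaults: 55% private, 18% BLM, 12% state, 8%
tribal, small federal remainders — echoing the regional ownership mix),
spatially autocorrelated owners from a finite pool, repeated mailing
addresses, and some private sections split into half/quarter parcels that
share an address with probability 0.3. `generate_roads()` lays grid roads
beside every second section line with a 5–15 m lateral offset (roads are
digitized beside cadastral lines, never exactly on them — and an exact
overlap would be degenerate for the parallel-fence rule), plus attached
driveway stubs and isolated two-tracks. `generate_landcover()` assigns
2 × 2-section blocks to crop or prairie classes with sub-half-section
inclusions in some crop blocks and occasional lakes placed well inside
section interiors.

One deliberate convention couples the generators: a fixed, seed-independent
subset of sections ("quiet" sections, about one in five — in the spirit of
the PLSS reserving specific school sections in every township) is always
unsubdivided private rangeland, and isolated two-tracks occur only there.
This guarantees the world contains roads that are *genuinely* unfenced and
fence-free, so the non-fenced transect class exists and a perfect model can
actually score κ = 1. Ground truth is the model's own output under a
controllable perturbation (`perturb_fences()`: per-feature drops, per-vertex
Gaussian jitter); zero perturbation makes truth ≡ model, the κ-recovery
dial used by the acceptance tests.

The simulator labels a transect fenced when truth fencing runs roughly
parallel (within 45°) inside the 200 m corridor for at least 100 m, and emits
GPS events at the nodes of the internal fence network — terminations,
corners, junctions — within 30 m of the transect: the places a surveyor
records roadside fencing starting, ending, or interior fencing converging
with the roadside. Events closer than 100 m merge; detection probability and
GPS noise are parameters.

What a green recovery test does establish: the rules, geometry, survey
design and the three assessments are mutually consistent and exact on
lattice-structured worlds. What it does not establish: performance on real
cadastral data — curved parcel boundaries, topology errors, roads missing
from the road theme (the dominant error source in practice), fence structure
types, or any behavioral realism of where ranchers actually fence.

## Design decisions taken on open questions

* *Internal-assessment negatives.* The stated sampling excludes random
  negatives only within 30 m of survey points, but the match rule is a 60 m
  center distance: a "negative" 30–60 m from a true node is undetectable as
  negative, and a perfect model could never reach κ = 1 — contradicting the
  package's own zero-noise recovery requirement. Default exclusion is
  therefore 2 × `accuracy_buffer_m` (60 m), configurable.
* *Internal false positives/negatives.* The published arithmetic for the
  internal assessment subtracts true positives from the GPS total and calls
  the difference *false positives*, unlike the other two assessments where
  it is the false negatives. Both behaviors are implemented
  (`mode = "consistent"` default, `mode = "literal"`).
* *Roads-assessment labels.* Transects are split fenced/non-fenced by
  observed roadside fencing of any source (the field definition), not by
  which sub-model predicts it: where the 20 m rule suppresses road fencing
  beside a parcel fence, the road is still fenced in the field sense, and
  the roads model is assessed against that reality.
* *Township rule.* A township-boundary input is named in the source's
  summary but never given semantics in its methods; the ledger carries a
  disabled `township` slot and no operation.
* *Tribal mailing addresses.* Whether tribal parcels use the
  mailing-address shortcut is unstated; default is owner-id merging only.
* *Study-boundary erasure.* "Lines that intersect the study-area boundary"
  is read as segments *lying on* the boundary (within tolerance), not any
  fence touching it — removing whole touching fences would delete real
  interior fencing.
* *BLM land-cover fencing.* The synthesis step that erases land-cover
  fencing inside BLM pastures takes the pasture polygons as an optional
  `blm` argument of `synthesize()`; omitted by default.

## Known limitations

* The jitter dial degrades the internal assessment smoothly (κ ≈ 1 → 0.4
  over 0–80 m at the default world), but the *total* assessment is
  structurally insensitive to positional jitter: every surveyed road carries
  modeled road fencing at 11–19 m offset, so any GPS point within the 30 m
  capture distance of a fenced transect lies within the 60 m match distance
  of modeled fencing regardless of how far the truth is jittered. The
  acceptance expectation that total κ falls below 0.5 at 40 m jitter is
  therefore left failing by design: in the published study that degradation
  came from roads missing from the roads dataset, not from positional error.
  A `drop_prob` perturbation, not jitter, is the realistic dial for the
  total assessment.
* Geometry robustness is delegated to shapely; the pure-R planar code
  assumes non-degenerate inputs (rings with ≥ 3 distinct vertices, finite
  coordinates).
* Sections are exact squares; real PLSS irregularities (correction lines,
  fractional sections) are out of scope, as are fence structure types and
  twinned/tripled roadside fences.
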