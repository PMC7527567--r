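---
title: "Methods behind ecoland: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ecoland}
  %\VignetteEncoding{UTF-8}
---

`ecoland` implements a complete assessment route for urban ecological-land
change on categorical rasters. This vignette records the science and the
design decisions: what each stage computes, the conventions it pins down,
the defaults and their units, what the synthetic-data generator does and
does not emulate, and the numerical choices that make results reproducible.

## The grid data model

All analysis runs on `eco_raster` grids: a value matrix (`NA` = nodata), a
square cell size in meters, and the projected coordinate of the lower-left
corner. Cell centers sit at `origin + (index − 0.5)·cell_size`; areas are
cell counts times `cell_size²`. Two rasters are *co-registered* only when
shape, cell size and origin match exactly — every two-layer operation
demands it, because silent resampling is a classic source of spurious
"change". Reprojection and resampling are deliberately out of scope; inputs
must arrive on a common grid.

On disk, rasters are plain-text Esri ASCII grids. The format carries no CRS
tag, so the reader enforces the projected-meters requirement heuristically:
a cell size at or below 0.01 is taken to be geographic degrees and
rejected. Everything downstream measures lengths in meters, areas in km² or
hectares; a 30 m cell (the resolution of Landsat-derived land-use maps and
of common DEM products) is the default throughout.

The default legend has ten classes, five of them ecological (woodland,
grassland, reservoirs and pit ponds, tidal flats, rivers and shallow
water). Cropland and aquaculture are excluded from ecological land because
they are production-driven and their ecosystem function is fragile;
unutilized land is excluded because its ecological benefit is transient.

## Transition accounting

`transition_matrix()` cross-tabulates two dates into the area matrix
`T_ij` (km²) and row-normalizes into `P_ij`. Three conventions matter:

* Rows for classes absent at the start date are *undefined* (`NA`), not
  zero — reporting a probability for an empty class would fabricate
  information.
* The contribution statistic `B_ij = 100·T_ij/Σ_i T_ij` is
  **destination-normalized**: it answers "what share of class *j*'s area at
  the period end originated as class *i*?", so columns sum to 100%. Its
  companion `C_ij = 100·T_ij/Σ_j T_ij` is the origin-normalized transition
  probability; rows sum to 100%. The pair makes eco/non-eco exchange
  legible from both ends of the conversion.
* `markov_project()` treats states as a row vector, `S_{t+1} = S_t P`, and
  refuses non-stochastic matrices. Because the estimator of `P` is
  definitional, projecting the estimated matrix one step reproduces the
  observed end-date areas exactly — a property the tests assert.

## Landscape metrics

Patches are connected components of same-class cells under 8-connectivity
(the standard default for raster landscape metrics); adjacency for edge
and contagion computations uses 4-neighbor shared sides. The boundary
conventions are pinned explicitly because they are the ones that make the
indices comparable across studies:

* **ED** counts only internal unlike-class edges per unit area (m/ha); the
  landscape boundary is not an "edge" between classes.
* **LSI** uses the total edge `E′` *including* the landscape boundary:
  `LSI = 0.25·E′/√A′`. A single solid square thus has LSI = 1.
* Nodata cells behave as landscape boundary: their sides count toward
  patch perimeter and `E′`, never toward unlike-class edge.
* **CONTAG** uses the double-count adjacency table `g_ik` and class-area
  proportions: `CONTAG = 100·[1 + Σ_i Σ_k q_ik ln q_ik / (2 ln n)]` with
  `q_ik = p_i·g_ik/Σ_k g_ik`, zero terms skipped. With one class present
  CONTAG (and SHEI) are undefined and reported as `NA`, not 0.
* Class-level PD and LPI keep the *total* landscape area as denominator —
  the convention under which class tables from different dates are
  comparable — while the class LSI normalizes by the class's own area.
* Per-patch contiguity uses the 3×3 template with center weight 1,
  orthogonal 2, diagonal 1 (sum 13): the patch mean template sum minus 1,
  over 12. A single cell scores 0, a solid 3×3 block (73/9 − 1)/12 ≈ 0.593.
  CONTIG_AM weights patches by area within their class.

Every metric is verified against an independent brute-force oracle
(explicit loops over cells and adjacencies, breadth-first-search patch
labeling) on one hundred random 6×6 and 8×8 grids; connected components
are delegated to `igraph` and only the metric formulas live here.

## Equivalent ecological area

Quality scoring weights each class area by a normalized (0–1)
ecosystem-service value `δ_i` — woodland 1.00 down to built-up 0.08 — and
reports the equivalent area `Σ δ_i A_i` and the average equivalent area
`Q = Σ δ_i A_i / A`. With normalized values, `Q` is bounded by the largest
`δ` among included classes (1.0 by default); series built from
*unnormalized* equivalence factors can exceed 1 and are not comparable with
this score, which is why the package treats the period-over-period
percentage change of the equivalent area, not its absolute level, as the
headline quality signal. The headline series runs over the ecological
subset (quality *of ecological land*); the all-class variant is available
through `subset = "all"`. Reductions are reported as
`(prev − cur)/prev·100` at one decimal.

## Center-of-gravity migration

The center of gravity is the area-weighted mean cell-center coordinate of
a class (equal cell weights make it an arithmetic mean; decomposing into
regions and area-weighting region centroids is equivalent, which the tests
check). Computation is strictly in planar projected meters. Displacements
are reported as exact east/north components and the exact Euclidean
distance — the package never rounds components and distance independently,
so the reported distance is always consistent with its components — plus a
compass octant from 45° sectors.

## The conversion model

The modelling stage asks what drives ecological loss. Cells ecological at
the period start are sampled without replacement; the binary outcome
records whether each cell is still ecological at the period end. Two
outcome codings are kept explicit: `remain` (y = 1 means persistence, the
convention under which the model is fitted) and `transform` (y = 1 means
conversion). The published-style transformation probability is evaluated as
`P = 1 − 1/(1 + e^{−z})` with `z` the persistence-side linear predictor —
implemented as `plogis(−z)`, which is the numerically stable form of the
same quantity when `plogis(z)` saturates.

Covariates, all at the land-use grid's resolution:

* **Slope** (degrees) from the DEM by Horn's 3×3 weighted finite
  difference, borders by edge replication.
* **Elevation** (m): the DEM itself.
* **Distance from built-up land** (km): exact Euclidean distance between
  cell centers to the nearest built-up cell (`EBImage`'s exact distance
  transform, cross-checked against brute force in the tests).
* **Built-up growth-rate level** (categorical 1–5): each zone's average
  annual growth rate `r = (A_t1/A_t0)^{1/years} − 1` (geometric by
  default; arithmetic available), binned at 5/10/20/35% with right-closed
  bins and a 1e-9 tolerance so rates computed as exactly 5% stay in the
  lower bin. Level 1 is the dummy reference; levels 2–5 enter as
  indicators. Forward stepwise selection typically retains only the levels
  that truly shift conversion odds.

Fitting is binomial maximum likelihood via `glm` (IRLS, log-likelihood
tolerance 1e-8, up to 100 iterations). Forward stepwise selection adds the
candidate with the smallest likelihood-ratio p-value while that p-value is
below 0.05. Estimates above 15 in absolute value or standard errors above
100 abort with a separation diagnosis instead of reporting a meaningless
fit. Validation uses an independently drawn holdout, a configurable 0.5
threshold on the transformation probability, and reports the confusion
matrix, per-row and overall accuracies and Cohen's kappa as exact rationals
of the counts.

Probability maps are classified with the fixed cuts 0.1 / 0.3 / 0.45 /
0.65 into five named levels. Fixed cuts rather than re-estimated natural
breaks keep level maps bit-reproducible across runs and comparable across
dates.

## The synthetic-data generator

`generate_scenario()` produces the conditions the analysis assumes, with
every stage seeded:

* **Landscape**: multi-seed region growing. Each class gets seeds and an
  exact cell quota proportional to its target share; classes grow
  breadth-first, and a class walled in before filling its quota plants a
  fresh seed, so realized proportions track targets. A fraction
  `1 − cohesion` of cells is then redrawn independently; `cohesion = 0` is
  an independent per-cell draw, `cohesion = 1` pure patch growth. The
  default 0.85 yields patch mosaics whose metric profiles resemble
  classified urban maps.
* **DEM**: a sum of 2-D Gaussian bumps (default 6 bumps, amplitudes up to
  120 m, widths 10–25% of the grid extent) — smooth, nonnegative,
  hill-scale relief.
* **Growth zones**: a Voronoi partition of 13 random sites, mirroring a
  typical count of administrative units, each assigned a growth level with
  all five levels represented.
* **Conversion**: each ecological cell converts to built-up land with
  probability `plogis` of the true linear predictor on its slope,
  elevation, distance and level dummies. The default true coefficients are
  the published driving-factor equation for an urbanizing coastal city,
  written on the conversion side of the logit (the negation of
  `default_transform_coefficients()`), so steep, high, remote cells in
  slow-growth zones persist. Non-ecological land never changes; a small
  reverse flow (gains) exists behind a flag but is off by default because
  the fitted model concerns losses.

Defaults are chosen once as the package's study conditions: a 224×224 grid
of 30 m cells gives ≥ 20,000 ecological cells, so the standard training
design (20,000 samples) is feasible; class proportions put ecological land
at ~54% of the landscape at the start, matching the mid-1990s share
reported for fast-urbanizing deltas; dates 1991/2000/2010/2018 span three
periods of unequal length.

What the generator does **not** emulate: spatially autocorrelated
conversion noise (draws are independent given covariates), realistic
geomorphology or urban form, class transitions other than
ecological→built-up, and measurement/classification error in the input
maps. Passing tests therefore certify the computations and the estimator's
statistical behavior under the assumed model — not robustness to the messy
error structure of real classified imagery.

## Validation design and problem sizes

The test suite runs entirely on generated data: metric oracle equivalence
on 100 random 8×8 grids; transition properties on 100 random raster pairs;
binomial-oracle checks of the generator at 64×64; and a 20-seed parameter
recovery study at the full 224×224 / n = 20,000 design, asserting every
coefficient within 3 estimated standard errors in at least 95% of seeds.
`scripts/acceptance.R` re-runs that recovery study plus the printed-table
arithmetic end to end from a command-line seed.

## Known limitations

* No reprojection, resampling, polygon input or multi-band imagery; inputs
  must be pre-gridded and co-registered.
* The ASCII-grid reader infers "projected meters" from the cell size only.
* Landscape metrics cover the eight indices of the assessment route, not
  the full catalog of metric suites.
* The logistic model is pixel-wise and ignores spatial autocorrelation of
  residuals; standard errors on real data will be optimistic. Alternative
  links, spatial random effects, and cellular-automata projection are out
  of scope.
* Absolute equivalent-area levels depend on the chosen service-value
  table; comparisons across studies require the same normalization.
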