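# ecoland

`ecoland` assesses how a city's **ecological land** — woodland, grassland,
reservoirs and pit ponds, tidal flats, and rivers and shallow water — changes
over time, from nothing more than co-registered categorical land-use rasters
for two or more dates plus a DEM. It is aimed at landscape ecologists and
urban planners who have classified land-use maps in hand and want the
complete quantitative assessment route in one reproducible package:

1. **Land-transformation accounting.** For each period the class-by-class
   area matrix `T_ij` and the row-normalized transition probability matrix
   `P_ij` (`0 ≤ P_ij ≤ 1`, `Σ_j P_ij = 1`), net change `A = A_b − A_a` per
   class, Markov projection `S_{t+1} = S_t P`, per-cell gain/loss maps, and
   the two percentage statistics used for eco/non-eco summaries: the
   origin-normalized transition probability `C_ij = 100·T_ij/Σ_j T_ij` and
   the destination-normalized contribution `B_ij = 100·T_ij/Σ_i T_ij`.
2. **Landscape pattern metrics**, computed from scratch on the raster grid:
   edge density (ED), patch density (PD), landscape shape index
   (`LSI = 0.25·E′/√A′`), largest patch index (LPI), contagion (CONTAG),
   Shannon diversity (`SHDI = −Σ p_i ln p_i`) and evenness
   (`SHEI = SHDI/ln n`) at landscape level, plus PD/LSI/LPI and the
   area-weighted mean contiguity index (CONTIG_AM) at class level.
3. **Ecological quality** via the equivalent ecological area: each class
   area weighted by its normalized (0–1) ecosystem-service value `δ_i`,
   with the average equivalent area `Q = Σ δ_i A_i / A` as a quality score.
4. **Center-of-gravity migration**: the area-weighted mean coordinate
   `X_t = Σ C_ti X_i / Σ C_ti` (and `Y_t`) of a class per date, with
   east/north displacement components, Euclidean distances and compass
   octants.
5. **Driving-factor modelling**: binomial logistic regression (forward
   stepwise, likelihood-ratio entry at p < 0.05) of whether an ecological
   cell persists, on slope, elevation, distance from built-up land and
   categorical built-up growth-rate levels; holdout validation with
   confusion matrix, accuracies and Cohen's kappa; and a mapped
   **transformation probability** `P = 1 − 1/(1+e^{−z})` classified into
   five fixed levels (≤0.1 low, ≤0.3 relatively low, ≤0.45 medium,
   ≤0.65 relatively high, >0.65 high).

A fully seeded synthetic-landscape generator (`synthetic_config()`,
`generate_scenario()`) emulates the statistical structure this analysis
assumes — cohesive patches of 10 classes, a smooth DEM, Voronoi growth
zones, and ecological-to-built-up conversion driven by a known logistic
model — so the entire route is testable end to end without any downloads.

Rasters are read and written as plain-text Esri ASCII grids in a projected
CRS with meter units; all tables are CSV.

## Worked example

```r
library(ecoland)
cfg <- synthetic_config(nrow = 96, ncol = 96, seed = 7)
b <- run_pipeline(cfg, n_train = 4000, n_holdout = 2000, quiet = TRUE)
report_summary(b, print = TRUE)
```

```
== Ecological land assessment summary ==

-- Net ecological-land change (km2) --
1991-2000: 4.5 -> 2.6 (net -1.9), C(eco->non-eco) = 42.6%, B = 33.6%
2000-2010: 2.6 -> 1.8 (net -0.8), C(eco->non-eco) = 31.2%, B = 12.4%
2010-2018: 1.8 -> 1.4 (net -0.4), C(eco->non-eco) = 23.1%, B = 5.9%

-- Landscape metrics (landscape level) --
1991: ED 192.0, PD 125.9, LSI 14.8, LPI 15.2, CONTAG 30.4, SHDI 2.0, SHEI 0.9
2000: ED 248.0, PD 123.9, LSI 18.9, LPI 36.7, CONTAG 34.4, SHDI 1.8, SHEI 0.8
2010: ED 215.6, PD 107.9, LSI 16.5, LPI 46.6, CONTAG 41.9, SHDI 1.6, SHEI 0.7
2018: ED 191.7, PD 95.7, LSI 14.8, LPI 51.6, CONTAG 46.7, SHDI 1.5, SHEI 0.6

-- Equivalent ecological area --
1991: 4.0 km2 (Q = 0.881)
2000: 2.3 km2 (Q = 0.887)
2010: 1.6 km2 (Q = 0.893)
2018: 1.2 km2 (Q = 0.896)
reductions: 1991-2000 42.2%, 2000-2010 30.7%, 2010-2018 22.8%

-- Center-of-gravity migration (ecological land) --
1991-2000: 239.8 m to the southeast
2000-2010: 176.8 m to the southeast
2010-2018: 105.1 m to the southeast

-- Conversion model --
included terms: elevation, level5, slope, level4
-2LL = 1900.4, LR chi2(4) = 1147.2
holdout overall accuracy = 81.4%, kappa = 0.540
mean transformation probability: woodland 0.730, grassland 0.913, reservoirs and pit ponds 0.500, tidal flats 0.849, rivers and shallow water 0.630
ecological-land mean = 0.702
```

Reading the output: ecological land on this synthetic scenario shrinks each
period, and the transition probability `C` (the chance that an ecological
cell converts) falls period over period while the contribution `B` (the
share of non-ecological land at the period end that used to be ecological)
falls with it. Rising CONTAG and LPI with falling SHDI show the landscape
aggregating as built-up land takes over. `Q` rises slightly because
low-value ecological classes convert first, concentrating the remaining
stock in high-value woodland. The stepwise fit recovers the covariates the
generator actually used, and the transformation-probability map scores
every remaining ecological cell.

`run_pipeline(cfg, out_dir = "out")` additionally writes every transition
matrix, metric table, quality and gravity series, model coefficient table
and probability/level raster, plus a JSON manifest with the seed, to `out/`.
A thin command-line wrapper with `simulate` / `run` / `report` subcommands
is installed at `inst/cli/ecoland.R`.

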