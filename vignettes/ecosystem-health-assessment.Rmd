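---
title: "Grid-based ecosystem-health assessment: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based ecosystem-health assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karsthealth)
```

## The problem and the model

Karst landscapes sit on soluble carbonate bedrock under thin, easily lost
soils; once vegetation is stripped, soil erodes to bare rock ("rocky
desertification") and recovery is slow. Mining prefectures in such terrain
concentrate three stressors at once — population, extraction, and
construction-land growth — and the question this package quantifies is how
ecosystem health responds to them, where, and over what time scale.

The core construct is a pressure–state–response (PSR) composite index on a
regular analysis grid. *Pressure* indicators measure the load human
activity places on the ecosystem, *state* indicators the current condition
and organization of the land mosaic, *response* indicators the capacity
and countermeasures that pull the system back toward health. Each
indicator is computed per grid cell per epoch, min–max normalized, and the
weighted sum

$$ESH = \sum_i W_i\,Q_i = P + S + R, \qquad \sum_i W_i = 1$$

is the ecosystem-health index, in $[0,1]$ by construction. The grid is a
2 × 2 km fishnet (`build_fishnet()`), chosen so that each cell aggregates
a 2 × 2 block of the nominal 1 km input rasters.

Model assumptions worth stating explicitly:

- indicators are linearly substitutable at fixed weights (a composite
  index assumption, inherited from the AHP weighting tradition);
- min–max normalization makes every indicator's contribution relative to
  the range observed *in the analysis*, not to absolute biophysical
  thresholds;
- a cell is a closed landscape for the within-cell metrics (SHDI, SHEI,
  contagion) — no moving window crosses cell borders;
- all inputs share one projected CRS and registration (the package
  deliberately does no reprojection).

## The indicator set

| layer | indicator | direction | weight | construction |
|---|---|---|---|---|
| pressure | population density | negative | 0.11 | zonal mean of the POP raster |
| pressure | man-made interference | negative | 0.14 | area-weighted coefficient sum |
| pressure | land reclamation rate | negative | 0.12 | farmland fraction |
| pressure | steep farmland (>25°) | negative | 0.05 | farmland pixels above slope threshold / all pixels |
| state | vegetation coverage | positive | 0.11 | vegetated-class fraction |
| state | Shannon evenness (SHEI) | positive | 0.03 | $SHDI/\ln m$ |
| state | Shannon diversity (SHDI) | positive | 0.03 | $-\sum p_k \ln p_k$ |
| state | contagion | positive | 0.03 | FRAGSTATS adjacency formula |
| state | resilience | positive | 0.10 | area-weighted coefficient sum |
| state | ecosystem-service value | positive | 0.13 | area-weighted coefficient sum |
| response | forest proportion | positive | 0.10 | forest+shrub fraction |
| response | rocky-desertification sensitivity | negative | 0.05 | banded slope/cover rule × carbonate fraction |

The weights are fixed inputs (an upstream analytic-hierarchy elicitation
is out of scope); they sum to exactly 1.00 with layer subtotals 0.42 /
0.43 / 0.15. Directions are a package decision where the source tradition
is implicit: all pressure indicators are negative (after normalization a
*high* subscore means *low* pressure, so higher is always healthier), and
rocky-desertification sensitivity is negative for the same reason.

Three indicators have no published formula and are implemented as
area-weighted per-class coefficient sums (`area_weighted_index()`), the
standard hemeroby / equivalent-value construction. The default tables
(`coefficient_table()`) are package conventions, deliberately
configurable: interference peaks at built-up land (1.0) and farmland
(0.6); resilience peaks at forest (0.9) and water (0.8); ecosystem-service
value follows the common Chinese equivalent-value pattern (water 1.0 >
forest 0.65 > … > built-up 0). Vegetation coverage is a land-cover
fraction, a documented proxy: no reflectance/NDVI processing is in scope.

Rocky-desertification sensitivity (`rds_rule()`) scores each cell as
*carbonate fraction × (slope-band score + cover-band score) / maximum
attainable score*. Default bands: slope 0–8–15–25°+ scoring 1–4, coverage
0.8–0.5–0.2 scoring 1–4 (sparser cover is more sensitive). The rule is a
susceptibility heuristic, not a process model; anything more would need
soil and lithology inputs the pipeline does not carry.

### Two properties of contagion worth knowing

The FRAGSTATS contagion formula is implemented exactly, with 4-neighbour
double-counted adjacencies per cell. Two consequences surprise first-time
users and are verified in the test suite: (i) its minimum 0 is attained at
*random-like* interspersion (uniform adjacency mass over class pairs), not
at a checkerboard — a two-class checkerboard concentrates all adjacency in
one off-diagonal pair and scores 50, the same as the infinite-aggregation
limit of the same composition; and (ii) at the 2 × 2-pixel cell size of
the nominal configuration, exact 0 values do occur. The range is therefore
$[0, 100]$, and single-class (or single-pixel) cells score 100 by
convention.

## Normalization, classification, and missing data

**Pooling.** Min/max for normalization are pooled over *all epochs
jointly* per indicator (default `pool = "all"`). This is required for
cross-year statements — "the state value rose" only means something if the
same raw value maps to the same $Q$ in every year. Per-epoch pooling is
retained as an option for single-epoch use.

**Degenerate indicators.** A constant indicator has no information;
`normalize_minmax()` maps it to $Q = 0.5$ everywhere with a warning rather
than failing, so one flat layer cannot take down a 12-indicator composite.
This matters in practice: in the default synthetic world the steep-farmland
indicator is constant 0, because a 1 km DEM with a 500 m relief amplitude
cannot produce Horn slopes above 25° (that would need ~470 m of elevation
change between adjacent pixel centers). Real dissected karst terrain does
exceed the threshold; a 1 km synthetic DEM is smoother than reality, and
this is a known divergence of the generator, not of the indicator.

**Classification.** `jenks_breaks()` is an exact Fisher–Jenks dynamic
program over the sorted unique values (weighted by multiplicity), so it is
deterministic and provably optimal — the test suite checks it against
exhaustive partition enumeration. Breaks are reported as class upper
bounds and classification intervals are left-open, so a value equal to a
break falls in the *lower* class. Breaks are computed on the pooled
multi-epoch ESH distribution (one legend for all years); the five classes
are labelled ill, unhealthy, middle, healthy, excellent healthy.

**Missing data.** Cells with no valid pixel are missing; missing
propagates through normalization (excluded from min/max), the composite,
the class maps, and is dropped listwise before spatial weights are built.
Mines falling on missing cells are tallied in an explicit "missing"
class so counts always partition the mine list.

## Spatial association

The spatial weights default to queen contiguity on the fishnet,
row-standardized — the default family of the common desktop tools for this
analysis; rook and k-nearest-neighbour schemes are available. The global
bivariate statistic is the z-score form
$I = \tfrac1n \sum_i z_{x,i} \sum_j w_{ij} z_{y,j}$ (population standard
deviations), which reduces to univariate Moran's I when $y = x$; the local
decomposition satisfies $\tfrac1n\sum_i I_i = I$ exactly.

Significance is by Monte-Carlo permutation (999 by default), permuting
the *second* variable over locations. Two p-values are reported:

- `pseudo_p` — one-sided in the direction of the observed sign,
  $(m+1)/(n_{perm}+1)$, the convention of the common GUI tools, with
  floor $0.001$ at 999 permutations;
- `p_two_sided` — the folded value $\min(1, 2\,\text{pseudo\_p})$.

The distinction matters for calibration: because the direction is chosen
*after* seeing the statistic, thresholding the one-sided pseudo-p at
$\alpha$ rejects in both tails and realizes a size near $2\alpha$ under
the null. A level-$\alpha$ test must threshold the folded value, and that
is what the package's null-calibration test does (500 i.i.d. replicates on
a 15 × 15 grid; the rejection count must sit in the binomial 99%
acceptance region around 0.05).

LISA significance uses conditional permutation: for each cell, the other
$n-1$ values are permuted and the cell's neighbour set redrawn, per
permutation. Cluster labels come from the signs of $z_{x,i}$ and the
spatial lag of $z_y$ — High–Low, for instance, is high urbanization on
unhealthy terrain — and cells with $p_i > \alpha$ are "not significant".

## The synthetic world

The generator's defaults define one fixed stated world, a desk-scale
stand-in for a karst mining prefecture; they were chosen once and are not
calibrated to any published real-data number (those require undeposited
rasters and are explicit non-goals).

| parameter | default | rationale |
|---|---|---|
| extent / resolution | 48 × 48 km at 1 km | desk-scale version of a ~10⁴ km² prefecture at the source data's resolution |
| epochs | 1990–2015, step 5 | the six-epoch series the analysis expects |
| classes | 8 ecological classes + built-up | the levels that carry ecological-value coefficients, plus construction land (level 0.0, below unused land — conversion to construction is the most ecologically negative transition; configurable) |
| urban centers | 3 | one dominant core plus secondary towns |
| mines | 66, in two 12 km belts on the first two centers | the typical mining-area count of the motivating setting; belts couple mining to the urban cores |
| carbonate fraction | 0.6318 | the karst share of the motivating setting |
| relief amplitude | 500 m over a 1400 m base | the stated elevation range of the motivating setting |
| urban boost | ×4 at kernel center, σ = 5 km | amplifies the regime's own built-up gain near centers; a regime with zero built-up gain (e.g. identity) is untouched, so Markov edge cases behave exactly |
| POP / GDP growth | ×1.15 / ×1.25 per epoch | steady urbanization; kernel amplitudes 2000 persons/km² and 15000 currency/person over low backgrounds |

The transition regimes (`default_regimes()`) are identity-dominated with
small flows: farmland→built-up throughout (doubled in the final interval,
the observed construction peak), forest/grass→farmland before 2000, and
farmland→forest/high-grass from 2000 on (the "grain-for-green" reversal).
Water and built-up are absorbing, so built-up area is non-decreasing by
construction. The initial mosaic is nearest-nucleus (Voronoi) assignment
of seeded class nuclei smoothed by a 3 × 3 majority filter — patchy,
spatially autocorrelated structure, which i.i.d. noise would not give and
the landscape metrics need.

**The coupled layout.** Mosaic nuclei within 1.6 kernel-σ of an urban
center are drawn from a disturbed "basin" mix (farmland, sparse grassland,
unused, no forest or water): cities and mining belts sit in agricultural
basins, not in forests. This implements the deliberate overlap of
urbanization kernels with low-state terrain that makes the downstream sign
checks (negative bivariate Moran's I; mine-zone ESH below the scene mean;
High–Low clusters under the kernels) properties of the construction rather
than accidents of a seed.

What the generator does *not* emulate: real class geometries and areas,
NDVI-resolution vegetation, terrain rough enough for >25° slopes at 1 km
(see above), socio-economic shocks (droughts, policy discontinuities), or
mine-specific degradation footprints beyond co-location with the disturbed
basin. A green test on this world therefore establishes that the
*machinery* is correct and that the stated qualitative structure is
recovered — not that any real region behaves this way.

Reproducibility: one scene seed; each stage (mosaic, transitions, DEM,
carbonate, mines) derives a deterministic child seed from it, so stages
are reproducible in isolation and a scene regenerates bit-identically.

## Numerical conventions

- **Geometry.** All coordinates in projected meters; raster row 1 is the
  northernmost; grid ids are row-major from the NW corner, 0-based. Cells
  are half-open, $[x, x+s) \times (y-s, y]$, so every point belongs to
  exactly one cell; pixel-to-cell assignment is by pixel center (1 km
  pixels nest exactly in 2 km cells in the nominal case, and the rule is
  unambiguous when they do not).
- **Slope.** Horn's 3 × 3 estimator with edge replication, the common GIS
  default; a single-pixel DEM has zero slope.
- **LCDM denominator.** $A$ is the *changed* (off-diagonal) area only.
  Including unchanged area would make scores incommensurable across
  intervals with different stability; with this choice the score is
  antisymmetric under reversing every transition and bounded by
  $100(\max D - \min D)$.
- **Steep-farmland denominator.** All valid pixels of the cell (not
  farmland pixels), so farmland-free cells score zero pressure rather
  than missing; the alternative reading is noted but not used.
- **Buffers.** A buffer is kept analytically as centers + radius:
  membership is a distance minimum, and the area integrates the union of
  y-chords over a fine x-scanline (midpoint rule, step r/2000; relative
  error well under the 0.1% tolerance used in tests). Zones at 2, 3 and
  6 km nest by construction; 2 km is the reported default as the radius
  with the least inter-mine overlap.
- **Boundary cells.** Cells extending past the stated extent are kept and
  flagged `boundary`; how straddling cells are treated is an analysis
  choice the caller can make by filtering on the flag.
- **Seeds.** Everything stochastic takes an explicit integer seed and
  restores the caller's RNG state; derived seeds stay below $2^{31}$.

## Known limitations

- No reprojection: inputs must share a CRS (reproject upstream with any
  standard GIS).
- Raster I/O is ESRI ASCII grid (plain text); binary GeoTIFF is out of
  scope in this environment.
- The per-cell landscape metrics use all of a cell's pixels as one
  landscape; with 2 × 2-pixel cells the metrics are coarse (SHDI at most
  $\ln 4$, contagion quantized) — a finer land-use raster sharpens them
  without code changes.
- The mine-buffer analysis weights every mine equally; production-capacity
  weighting would need data the pipeline does not carry.
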