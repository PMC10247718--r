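---
title: "Mapping crop-specific phosphorus application rates from administrative statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping crop-specific phosphorus application rates from administrative statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosgrid)
```

## The problem

Fertilizer application rates in China are published at two incompatible
resolutions. Provincial cost-benefit yearbooks report *crop-specific*
rates (kg/ha of phosphorus fertilizer and of multi-nutrient compound
— "component" — fertilizer) for rice, wheat and maize. County yearbooks
report only *total* fertilizer consumption, plus crop-specific and total
sown areas, for roughly two thousand counties. Neither source alone
supports a crop-specific, kilometre-scale map of phosphorus input: the
provincial rates lump enormous within-province variation, and the county
totals carry no crop structure.

`phosgrid` reconciles the two levels with a conservative allocation
scheme: the provincial crop structure decides *how* a county's total is
split across crops, while the county's own total decides *how much* is
applied. The result is a county-year-crop table of P~2~O~5~ rates and,
through crop growing-area masks, one 1 km GeoTIFF per crop-year.

## The allocation model

For crop $i$, county $j$ (in province $p$) and year $y$, with provincial
rates $FR_{i,p,y}$, county crop areas $A_{i,j,y}$ and the county total
consumption $FC_{j,y}$ (each computed separately for the two fertilizer
kinds):

$$\mathrm{Rat}_{i,j,y} = \frac{FR_{i,p,y}\,A_{i,j,y}}
  {\sum_i FR_{i,p,y}\,A_{i,j,y}}, \qquad
FC_{i,j,y} = \mathrm{Rat}_{i,j,y}\,FC_{j,y}, \qquad
FR_{i,j,y} = \frac{FC_{i,j,y}}{A_{i,j,y}}.$$

Two algebraic properties make this preferable to directly multiplying
provincial rates with county areas:

* **Mass conservation.** The ratios of a county-year sum to one, so
  $\sum_i FC_{i,j,y} = FC_{j,y}$ exactly — the county total from the
  yearbook is never inflated or deflated, which also protects provincial
  and national aggregates.
* **Exact collapse under uniformity.** If every county in a province
  truly applied the provincial rates and the county totals are consistent
  with that ($FC_{j,y} = \sum_i FR_{i,p,y} A_{i,j,y}$), the three
  equations collapse to $FR_{i,j,y} = FR_{i,p,y}$. The test suite checks
  this *exact-recovery* property to 1e-9 relative on generated worlds.

The four crop categories are rice, wheat, maize and a residual "other"
category. The other-crops provincial rate is itself derived: named-crop
consumption (rate × area) is subtracted from the provincial total and the
residual is divided by the residual sown area. Because the inputs come
from different statistical systems the residual can be negative; it is
then clamped to zero and flagged (`"clamped"`), never propagated as
negative mass. A positive residual over zero residual area yields no rate
(`"undefined"`), and counties in such provinces fall back to allocating
over the three named crops (`"no_other_rate"`), rather than being
discarded wholesale.

## Units

Everything is held internally in grams, square metres and g/m²
(g P~2~O~5~ m^-2^ after conversion). The yearbooks' native units are not
standardized, so `read_statistics()` requires an explicit unit
configuration (`kg_per_ha`, `kg_per_mu`, `t`, `khm2`, ...) instead of
guessing; conversions are exact (1 mu = 1/15 ha, so 1 kg/mu = 1.5 g/m²)
and invertible.

## Gap filling

County series have sporadic missing years. Missing runs of at most
`max_run = 2` consecutive years (data unavailable for *fewer than three*
consecutive years) are filled with a natural cubic spline through the
observed annual values; longer runs and gaps touching the series
boundary stay missing and the affected county-years are excluded from
the maps (NoData). Design choices, made once:

* **What is filled.** The *inputs* of the allocation — the two county
  total-consumption series and the four area series — are filled; ratios
  and rates are always recomputed from filled inputs. Interpolating
  ratios or rates directly would break mass conservation after the fill.
* **Boundary conditions.** Natural (zero second derivative) ends; no
  extrapolation beyond the observed span by default. This is the
  least-assumption cubic spline and keeps fills inside the observed
  period.
* **Floors.** Filled values below zero (spline ringing near spikes) are
  clamped to zero: consumptions and areas are non-negative quantities.
* **Degenerate series.** A series with fewer than four observations
  cannot support a cubic spline; at the single-series level this is an
  error, at the table level the county keeps its gaps and the event is
  logged, so one bad county does not abort a national build.

## P~2~O~5~ conversion

Phosphorus-fertilizer statistics are already P~2~O~5~ mass. Component
fertilizer is gross product mass and is converted with a year-specific
weighted content: national import/domestic shares (bundled as an
editable CSV, 2004–2016) weighting the two product contents, 60.0%
(imported) and 30.8% (domestic). For example 2004, with shares
36.0%/64.0%, gives $0.36 \times 0.600 + 0.64 \times 0.308 = 0.41312$.
The combined county rate is
`rate_phosphorus + rate_component * content(year)`. For comparisons with
datasets reported in elemental P, `p_mass_to_p2o5()` applies the exact
molar ratio 142/62. The conversion assumes the yearbook component
statistics quantify gross product mass; a single national content per
year is a recognized simplification (no within-year or within-province
composition variation).

## Gridding

County membership of a pixel comes from a supplied county-ID raster —
never re-derived from polygon geometry — so the masking step is
deterministic. A crop-year map assigns every pixel inside the crop's
growing-area mask the P~2~O~5~ rate of its county; everything else
(outside the mask, outside counties, counties with undefined or dropped
rates) is NoData. Maps are single-band Float32 GeoTIFFs, WGS84
geographic (EPSG:4326), north-up, pixel-center convention, NoData -9999
recorded in the GDAL_NODATA tag, named `CNP_<crop>_<year>.tif`. The
GeoTIFF reader/writer is a deliberately minimal implementation of
exactly this profile (uncompressed, single band, little-endian) and its
payload is cross-checked in the tests against an independent TIFF
reader. Because the band is Float32, a write/read round trip is
bit-exact at Float32 precision; `as_float32()` reproduces that
quantization for comparisons.

## Summary statistics

`national_series()` computes annual national means as county rates
weighted by county growing areas; sub-crop variants (e.g. single/double
season rice) are pooled by passing several categories, which weights
them by area in the same sum. `map_national_series()` is the map-based
path (pixel-count weighting); the suite cross-checks the two paths.
`relative_trend()` regresses the annual means on calendar year (OLS),
reports the two-sided slope t-test, and defines the relative trend as
100 × slope / period mean — the denominator convention is stated
explicitly because "% yr^-1^" does not determine it. Zero-residual fits
are flagged degenerate (p = 1 for a constant series, p = 0 for an exact
non-constant line) instead of emitting 0/0. `tukey_hsd()` compares crops
in a one-way layout whose replicates are the annual national means
(n = 13 per crop — the only national-level sample the summary table can
use), with studentized-range pairwise p-values and a compact letter
display at α = 0.05. `total_consumption_series()` and
`per_cropland_rate_map()` provide the aggregate series and per-cropland
map used for dataset intercomparison; cropland (physical land, possibly
multi-cropped) is kept distinct from sown area throughout.

## The synthetic world

Real yearbook statistics are not redistributable, so the package ships a
generator that emulates their structure: 31 provinces of 60–70 counties
(~2000 counties), years 2004–2016, four crop categories, county sown
areas of 2×10^7^–2×10^8^ m², rates of a few g/m² with -1% to +3% yr^-1^
polynomial trends, sporadic missing county-years (default probability
0.05, runs ≤ 2), counties as rectangular tiles on the grid, and crop
masks marking the tiles of counties with positive growing area. All
statistics tables are derived from the drawn ground truth, so they are
exactly consistent (county totals close over crops; provincial tables
are county sums / area-weighted means).

Two flavors separate what can and cannot be asserted:
`"provincial_uniform"` worlds (county truth equals provincial rates) are
the exact-recovery regime; `"heterogeneous"` worlds (county truth varies
±30% within provinces) are the regime where only conservation — not
per-crop county truth — is recoverable, which is precisely the
allocation scheme's stated guarantee. `perturb_world()` injects the
three pathologies (named-crop overshoot, zero-area county with positive
consumption, over-long gap) that drive the edge-case policies.

What the generator does **not** emulate: real administrative geography,
reporting biases or systematic under-coverage of the yearbooks,
within-county heterogeneity, and statistical-caliber mismatches between
the provincial and county systems beyond what the heterogeneous flavor
induces. Passing tests therefore demonstrate the pipeline's algebraic
correctness and edge-case behavior, not the accuracy of any real-world
dataset built with it.

## Problem sizes and numerical choices

The test suite runs on small worlds (2 provinces × 10 counties × 13
years for the conservation and recovery suites; a 200×200 grid for the
gridding oracle), chosen as the smallest sizes that exercise every code
path; the acceptance script runs the full default scale (~2000
counties). Deterministic summation uses the fixed crop enumeration
(rice, wheat, maize, other). Conservation and recovery are asserted at
1e-9 relative; ratio normalization at 1e-12; all randomness is seeded
through `world_config()`.

## Known limitations

* The allocation transfers the provincial crop *structure* to counties;
  within-province differences in crop-specific intensity are
  irrecoverable from these statistics by construction.
* A single national component-fertilizer composition per year.
* The GeoTIFF support reads the profile it writes (plus simple striped
  Float32 files); it is not a general TIFF library.
* No spatial smoothing or borrowing across counties, and no sub-county
  redistribution: a county is a single value per crop-year.
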