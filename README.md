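# phosgrid

Crop-specific phosphorus application-rate mapping from administrative
fertilizer statistics.

## The problem

Chinese fertilizer statistics come at two incompatible resolutions:
provincial yearbooks publish **crop-specific** application rates of
phosphorus and compound ("component") fertilizer for rice, wheat and
maize, while county yearbooks publish only each county's **total**
fertilizer consumption together with crop-specific and total sown
areas. `phosgrid` harmonizes the two so that researchers in nutrient
accounting, agricultural modeling and phosphorus-pollution analysis can
build crop-specific, kilometre-scale P₂O₅ rate maps whose county,
provincial and national mass balances all close.

## The method

For crop *i*, county *j* in province *p*, year *y*, and each fertilizer
kind separately, provincial rates FRᵢ,ₚ,ᵧ and county areas Aᵢ,ⱼ,ᵧ define
allocation ratios that split the county total FCⱼ,ᵧ:

    Rat_ijy = FR_ipy · A_ijy / Σᵢ FR_ipy · A_ijy
    FC_ijy  = Rat_ijy · FC_jy
    FR_ijy  = FC_ijy / A_ijy

Because the ratios sum to one, county totals are conserved exactly; and
when a province's counties truly share the provincial rates, the three
equations collapse so that the county rates recover them exactly. Around
this core the package provides:

* the residual **other-crops** provincial rate (total minus named-crop
  consumption over residual area, with clamped/undefined policies),
* **natural cubic-spline gap-filling** of county series (interior runs
  of ≤ 2 missing years only),
* **P₂O₅ conversion** of component fertilizer by year-specific
  import/domestic weighting (60.0% vs 30.8% P₂O₅ content) and the exact
  142/62 elemental-P conversion,
* **gridding** onto 1 km WGS84 GeoTIFFs (`CNP_<crop>_<year>.tif`,
  Float32, NoData -9999) via a county-ID raster and crop growing-area
  masks,
* **summary statistics**: area-weighted national annual means, % yr⁻¹
  trends with slope t-tests, Tukey HSD contrasts with compact letters,
  total-consumption series and per-cropland rate maps,
* a seeded **synthetic-world generator** (provinces, counties, tables,
  rasters with known ground truth) so the whole pipeline is testable
  without the non-redistributable yearbooks.

## Worked example

```r
library(phosgrid)

cfg <- world_config(n_provinces = 3, counties_per_province = c(8, 8),
                    grid = list(nrow = 24, ncol = 24, px = 0.01,
                                xmin = 100, ymax = 40),
                    missing_rate = 0.05, flavor = "heterogeneous",
                    seed = 42)
world <- generate_world(cfg)
res <- run_pipeline_world(world)

head(res$rates[!is.na(res$rates$p2o5_rate), ], 4)
#>   county year  crop rate_phosphorus rate_component p2o5_rate flag_p2o5
#> 1  C0001 2004  rice        8.168115      12.518434 13.339730   derived
#> 2  C0001 2004 wheat        6.137262      10.130259 10.322274   derived
#> 3  C0001 2004 maize        6.718775       7.657679  9.882316   derived
#> 4  C0001 2004 other        3.332735       2.285541  4.276938   derived
```

Each row is one county-year-crop: the per-kind rates (g/m² of P₂O₅ for
phosphorus fertilizer, g/m² of product for component fertilizer), the
combined `p2o5_rate` in g P₂O₅ m⁻², and a provenance flag
(`derived` / `gap_filled` / `clamped` / `undefined` / ...).

```r
s <- national_series(res$rates, res$county_filled, "wheat")
relative_trend(s)
#>    crop      slope      p_value period_mean relative_trend degenerate
#> 1 wheat 0.08966593 8.324182e-06    8.514251       1.053128      FALSE
```

The national wheat rate averages 8.51 g P₂O₅ m⁻² over 2004–2016 and
rises by 1.05% per year (OLS slope 0.090 g m⁻² yr⁻¹, p ≈ 8e-6).

```r
series <- lapply(setNames(nm = named_crops()),
                 function(cr) national_series(res$rates, res$county_filled, cr))
tukey_hsd(series)$letters
#>  rice wheat maize
#>   "a"   "b"   "b"
```

Crops sharing a letter are not significantly different at p < 0.05; in
this world rice differs from wheat and maize.

```r
m <- rasterize_rates(res$rates, world$county_raster,
                     world$crop_masks$wheat[["2016"]], "wheat", 2016)
write_ratemap(m, "maps")
#> maps/CNP_wheat_2016.tif   (304 finite pixels, NoData -9999, EPSG:4326)
```

Real statistics enter through `read_statistics()` (long-format CSVs with
an explicit unit configuration, e.g. `kg_per_ha` / `t` / `khm2`) in
place of the generated tables.

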