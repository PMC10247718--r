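Package: phosgrid
Title: Crop-Specific Phosphorus Application-Rate Mapping from Administrative Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes coarse provincial crop-specific fertilizer-rate
    statistics with fine county-level total-consumption and sown-area
    statistics through a mass-conserving allocation scheme, converts
    phosphorus and compound ("component") fertilizer quantities to P2O5,
    and projects the resulting county crop-specific phosphorus rates onto
    1 km GeoTIFF grids. Includes natural cubic-spline gap-filling of county
    time series, area-weighted national aggregation with trend tests and
    Tukey HSD contrasts, and a deterministic synthetic-world generator
    (provinces, counties, statistics tables, rasters with known ground
    truth) so that every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    jsonlite
Config/testthat/edition: 3
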