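#' Rasterize county values onto a masked grid
#'
#' Shared core of the gridding stage: every pixel takes the value of the
#' county it belongs to (membership from the supplied county-ID raster,
#' never re-derived from geometry) wherever the mask marks presence; all
#' other pixels — outside the mask, outside any county, or in a county
#' without a defined value — are NA. County IDs present in the raster but
#' absent from the value table are emitted as NA and counted in the
#' `"n_unknown_county"` attribute.
#'
#' @param values named numeric vector: county id -> value (NA allowed).
#' @param county_raster a [phos_raster()] of integer county indices with
#'   attribute `"county_ids"` mapping index to county id.
#' @param mask a [phos_raster()]; pixels with value > 0 are present.
#' @return a [phos_raster()] of values with NA elsewhere.
#' @export
rasterize_county_values <- function(values, county_raster, mask) {
  stopifnot(inherits(county_raster, "phos_raster"),
            inherits(mask, "phos_raster"))
  if (!same_geometry(county_raster$geom, mask$geom)) {
    stop("county raster and mask do not share grid geometry", call. = FALSE)
  }
  ids <- attr(county_raster, "county_ids")
  if (is.null(ids)) stop("county raster lacks the county_ids attribute",
                         call. = FALSE)
  idx <- county_raster$values
  lut <- values[match(ids, names(values))]   # per county index
  unknown <- is.na(match(ids, names(values)))
  v <- matrix(NA_real_, county_raster$geom$nrow, county_raster$geom$ncol)
  present <- !is.na(idx) & !is.na(mask$values) & mask$values > 0
  v[present] <- lut[idx[present]]
  out <- phos_raster(v, county_raster$geom)
  attr(out, "n_unknown_county") <- sum(unknown[unique(idx[present])],
                                       na.rm = TRUE)
  out
}

#' Gridded crop-specific P2O5 rate map
#'
#' Projects the harmonized county P2O5 rates for one crop-year onto the
#' grid: pixels inside the crop's growing-area mask take their county's
#' rate; everything else is NoData. Only records with a defined, finite
#' `p2o5_rate` contribute (dropped/undefined/missing county-years become
#' NoData).
#'
#' @param rates county rate table with `p2o5_rate` (see
#'   [total_p2o5_rate()]).
#' @param county_raster county-ID raster (see
#'   [rasterize_county_values()]).
#' @param crop_mask presence raster for the crop-year; must share the
#'   county raster's geometry exactly.
#' @param crop,year the crop category and year to map.
#' @return a `rate_map`: a [phos_raster()] with attributes `crop`, `year`.
#' @export
rasterize_rates <- function(rates, county_raster, crop_mask, crop, year) {
  stopifnot(crop %in% crop_categories(), length(year) == 1L)
  sub <- rates[rates$crop == crop & rates$year == year &
                 !is.na(rates$p2o5_rate) & is.finite(rates$p2o5_rate), ]
  if (any(sub$p2o5_rate < 0)) stop("negative P2O5 rate", call. = FALSE)
  vals <- setNames(sub$p2o5_rate, sub$county)
  out <- rasterize_county_values(vals, county_raster, crop_mask)
  attr(out, "crop") <- crop
  attr(out, "year") <- as.integer(year)
  class(out) <- c("rate_map", class(out))
  out
}

#' Write a rate map as a GeoTIFF with the canonical file name
#'
#' Files are named `CNP_<crop>_<year>.tif` and written as single-band
#' Float32 WGS84 GeoTIFFs with NoData -9999 (see [write_geotiff()]).
#'
#' @param map a `rate_map` from [rasterize_rates()].
#' @param dir output directory (created if needed).
#' @param nodata NoData sentinel.
#' @return the file path, invisibly.
#' @export
write_ratemap <- function(map, dir, nodata = -9999) {
  stopifnot(inherits(map, "rate_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("CNP_%s_%d.tif", attr(map, "crop"),
                                 attr(map, "year")))
  write_geotiff(map, path, nodata = nodata)
  invisible(path)
}

#' Read a rate map written by [write_ratemap()]
#'
#' @param path `CNP_<crop>_<year>.tif` path.
#' @return a `rate_map` with NoData pixels as NA; attributes `crop` and
#'   `year` parsed from the file name, `nodata` and `epsg` from the tags.
#' @export
read_ratemap <- function(path) {
  g <- read_geotiff(path)
  v <- g$raster$values
  if (!is.na(g$nodata)) v[v == g$nodata] <- NA_real_
  out <- phos_raster(v, g$raster$geom)
  m <- regmatches(basename(path),
                  regexec("^CNP_([a-z]+)_([0-9]{4})\\.tif$", basename(path)))[[1]]
  if (length(m) == 3L) {
    attr(out, "crop") <- m[2]
    attr(out, "year") <- as.integer(m[3])
  }
  attr(out, "nodata") <- g$nodata
  attr(out, "epsg") <- g$epsg
  class(out) <- c("rate_map", class(out))
  out
}

#' Write the full set of crop-year rate maps
#'
#' @param rates county rate table with `p2o5_rate`.
#' @param world_rasters list with `county_raster` and `crop_masks` (as in a
#'   [generate_world()] world).
#' @param dir output directory.
#' @param crops,years which maps to write (defaults: the three mapped
#'   crops, all years present in `rates`).
#' @return character vector of paths, invisibly.
#' @export
write_all_ratemaps <- function(rates, world_rasters, dir,
                               crops = named_crops(),
                               years = sort(unique(rates$year))) {
  paths <- character(0)
  for (cr in crops) {
    for (y in years) {
      mask <- world_rasters$crop_masks[[cr]][[as.character(y)]]
      if (is.null(mask)) next
      map <- rasterize_rates(rates, world_rasters$county_raster, mask, cr, y)
      paths <- c(paths, write_ratemap(map, dir))
    }
  }
  invisible(paths)
}
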