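#' Grid geometry for rasters
#'
#' North-up WGS84 geographic grid described by its dimensions, upper-left
#' corner and square pixel size in degrees. Pixel (1, 1) is the north-west
#' pixel; coordinate/index mapping uses the pixel-center convention.
#'
#' @param nrow,ncol grid dimensions.
#' @param xmin longitude of the left edge (degrees).
#' @param ymax latitude of the top edge (degrees).
#' @param px pixel size (degrees).
#' @return a `grid_geom` list.
#' @export
grid_geometry <- function(nrow, ncol, xmin, ymax, px) {
  stopifnot(nrow >= 1, ncol >= 1, px > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 xmin = as.numeric(xmin), ymax = as.numeric(ymax),
                 px = as.numeric(px)),
            class = "grid_geom")
}

#' @rdname grid_geometry
#' @param a,b two `grid_geom` objects.
#' @export
same_geometry <- function(a, b) {
  isTRUE(a$nrow == b$nrow && a$ncol == b$ncol && a$xmin == b$xmin &&
           a$ymax == b$ymax && a$px == b$px)
}

#' A raster layer: a value matrix plus grid geometry
#'
#' @param values matrix (`geom$nrow` x `geom$ncol`), row 1 = northernmost.
#' @param geom a [grid_geometry()].
#' @return a `phos_raster` list.
#' @export
phos_raster <- function(values, geom) {
  stopifnot(inherits(geom, "grid_geom"),
            nrow(values) == geom$nrow, ncol(values) == geom$ncol)
  structure(list(values = values, geom = geom), class = "phos_raster")
}

#' Round a numeric vector or matrix through IEEE 32-bit float precision
#'
#' GeoTIFF bands are written as Float32; this reproduces the quantization
#' a write/read round trip applies, so in-memory values can be compared
#' bit-exactly against read-back values.
#'
#' @param x numeric vector or matrix.
#' @return `x` with every value rounded to the nearest representable
#'   float32.
#' @export
as_float32 <- function(x) {
  out <- readBin(writeBin(as.vector(as.numeric(x)), raw(), size = 4L,
                          endian = "little"),
                 "numeric", n = length(x), size = 4L, endian = "little")
  if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x))
  out
}

# ---- minimal single-band Float32 GeoTIFF ----------------------------------
# Uncompressed little-endian TIFF, one strip, with the GeoTIFF tags needed
# for a north-up WGS84 geographic grid (ModelPixelScale, ModelTiepoint,
# GeoKeyDirectory) and the GDAL_NODATA ASCII tag.

.TT_ASCII <- 2L; .TT_SHORT <- 3L; .TT_LONG <- 4L; .TT_DOUBLE <- 12L

#' Write a single-band Float32 GeoTIFF
#'
#' Values are stored uncompressed in one strip, row-major from the north
#' row, in IEEE float32. Georeferencing is recorded with the
#' ModelPixelScale and ModelTiepoint tags plus a GeoKey directory declaring
#' a geographic WGS84 (EPSG:4326) system; the NoData value goes into the
#' GDAL_NODATA ASCII tag. NA values are written as `nodata`.
#'
#' @param raster a [phos_raster()] (numeric values).
#' @param path output `.tif` path.
#' @param nodata NoData sentinel written to the file.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "phos_raster"))
  g <- raster$geom
  v <- raster$values
  v[is.na(v)] <- nodata
  n <- g$nrow * g$ncol
  data_bytes <- 4L * n
  data_offset <- 8L
  ifd_offset <- data_offset + data_bytes
  if (ifd_offset %% 2L == 1L) ifd_offset <- ifd_offset + 1L

  nodata_str <- sprintf("%g", nodata)
  nodata_raw <- c(charToRaw(nodata_str), as.raw(0L))
  geokeys <- as.integer(c(1, 1, 0, 4,
                          1024, 0, 1, 2,     # model type: geographic
                          1025, 0, 1, 1,     # raster type: pixel-is-area
                          2048, 0, 1, 4326,  # geographic CRS: WGS84
                          2054, 0, 1, 9102)) # angular unit: degree
  pixelscale <- c(g$px, g$px, 0)
  tiepoint <- c(0, 0, 0, g$xmin, g$ymax, 0)

  entries <- list(
    list(256L, .TT_LONG, 1L, g$ncol),
    list(257L, .TT_LONG, 1L, g$nrow),
    list(258L, .TT_SHORT, 1L, 32L),
    list(259L, .TT_SHORT, 1L, 1L),
    list(262L, .TT_SHORT, 1L, 1L),
    list(273L, .TT_LONG, 1L, data_offset),
    list(277L, .TT_SHORT, 1L, 1L),
    list(278L, .TT_LONG, 1L, g$nrow),
    list(279L, .TT_LONG, 1L, data_bytes),
    list(339L, .TT_SHORT, 1L, 3L),
    list(33550L, .TT_DOUBLE, 3L, pixelscale),
    list(33922L, .TT_DOUBLE, 6L, tiepoint),
    list(34735L, .TT_SHORT, length(geokeys), geokeys),
    list(42113L, .TT_ASCII, length(nodata_raw), nodata_raw)
  )
  n_entries <- length(entries)
  aux_offset <- ifd_offset + 2L + 12L * n_entries + 4L

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4L, endian = "little")
  # pixel payload, row-major from the top row, float32
  writeBin(as.numeric(t(v)), con, size = 4L, endian = "little")
  if ((data_offset + data_bytes) %% 2L == 1L) writeBin(as.raw(0L), con)

  type_bytes <- c(`2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  aux <- list()
  cur_aux <- aux_offset
  writeBin(as.integer(n_entries), con, size = 2L, endian = "little")
  for (e in entries) {
    tag <- e[[1]]; type <- e[[2]]; count <- e[[3]]; val <- e[[4]]
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    nbytes <- type_bytes[[as.character(type)]] * count
    if (nbytes <= 4L) {
      # inline value, left-justified in the 4-byte field
      field <- raw(4L)
      enc <- if (type == .TT_SHORT) {
        writeBin(as.integer(val), raw(), size = 2L, endian = "little")
      } else if (type == .TT_LONG) {
        writeBin(as.integer(val), raw(), size = 4L, endian = "little")
      } else if (type == .TT_ASCII) {
        as.raw(val)
      } else {
        stop("inline type not handled")
      }
      field[seq_along(enc)] <- enc
      writeBin(field, con)
    } else {
      writeBin(as.integer(cur_aux), con, size = 4L, endian = "little")
      aux[[length(aux) + 1L]] <- e
      cur_aux <- cur_aux + nbytes + nbytes %% 2L
    }
  }
  writeBin(0L, con, size = 4L, endian = "little")  # no further IFD
  for (e in aux) {
    type <- e[[2]]; val <- e[[4]]
    if (type == .TT_DOUBLE) {
      writeBin(as.numeric(val), con, size = 8L, endian = "little")
    } else if (type == .TT_SHORT) {
      writeBin(as.integer(val), con, size = 2L, endian = "little")
      if ((2L * length(val)) %% 2L == 1L) writeBin(as.raw(0L), con)
    } else if (type == .TT_ASCII) {
      writeBin(as.raw(val), con)
      if (length(val) %% 2L == 1L) writeBin(as.raw(0L), con)
    }
  }
  invisible(path)
}

#' Read a GeoTIFF written by [write_geotiff()]
#'
#' Parses the IFD of a little-endian, uncompressed, single-band Float32
#' TIFF (one or more strips), reconstructs the grid geometry from the
#' ModelPixelScale/ModelTiepoint tags and the NoData value from the
#' GDAL_NODATA tag, and checks that the GeoKey directory declares
#' EPSG:4326.
#'
#' @param path `.tif` path.
#' @return list with `raster` (a [phos_raster()]; values as stored, NoData
#'   not substituted), `nodata`, and `epsg`.
#' @export
read_geotiff <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  rd <- function(off, type, n) {
    size <- c(numeric = 4L, integer = 4L, short = 2L, double = 8L)
    switch(type,
      short = readBin(buf[(off + 1L):length(buf)], "integer", n = n,
                      size = 2L, endian = "little", signed = FALSE),
      long = readBin(buf[(off + 1L):length(buf)], "integer", n = n,
                     size = 4L, endian = "little"),
      double = readBin(buf[(off + 1L):length(buf)], "numeric", n = n,
                       size = 8L, endian = "little"),
      float = readBin(buf[(off + 1L):length(buf)], "numeric", n = n,
                      size = 4L, endian = "little"))
  }
  if (rawToChar(buf[1:2]) != "II" || rd(2L, "short", 1L) != 42L) {
    stop("not a little-endian TIFF: ", path, call. = FALSE)
  }
  ifd <- rd(4L, "long", 1L)
  n_entries <- rd(ifd, "short", 1L)
  tags <- list()
  type_bytes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  for (i in seq_len(n_entries)) {
    base <- ifd + 2L + 12L * (i - 1L)
    tag <- rd(base, "short", 1L)
    type <- rd(base + 2L, "short", 1L)
    count <- rd(base + 4L, "long", 1L)
    nbytes <- type_bytes[[as.character(type)]] * count
    voff <- if (nbytes <= 4L) base + 8L else rd(base + 8L, "long", 1L)
    val <- if (type == 3L) rd(voff, "short", count)
      else if (type == 4L) rd(voff, "long", count)
      else if (type == 12L) rd(voff, "double", count)
      else if (type %in% c(1L, 2L)) buf[(voff + 1L):(voff + count)]
      else stop("unhandled TIFF tag type ", type)
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("required TIFF tag ", tag, " missing", call. = FALSE)
    v
  }
  ncol <- need(256L); nrow <- need(257L)
  if (need(258L) != 32L || is.null(tags[["339"]]) || tags[["339"]] != 3L) {
    stop("expected a Float32 band", call. = FALSE)
  }
  if (need(259L) != 1L) stop("compressed TIFF not supported", call. = FALSE)
  offsets <- need(273L); counts <- need(279L)
  vals <- unlist(lapply(seq_along(offsets), function(s) {
    rd(offsets[s], "float", counts[s] %/% 4L)
  }))
  values <- matrix(vals, nrow = nrow, ncol = ncol, byrow = TRUE)

  scale <- need(33550L); tie <- need(33922L)
  geom <- grid_geometry(nrow, ncol, xmin = tie[4], ymax = tie[5],
                        px = scale[1])
  geokeys <- tags[["34735"]]
  epsg <- NA_integer_
  if (!is.null(geokeys) && length(geokeys) >= 4L) {
    nk <- geokeys[4]
    for (k in seq_len(nk)) {
      key <- geokeys[4L * k + 1L]
      if (key == 2048L) epsg <- geokeys[4L * k + 4L]
    }
  }
  nodata <- tags[["42113"]]
  nodata <- if (is.null(nodata)) NA_real_ else {
    as.numeric(rawToChar(nodata[nodata != as.raw(0L)]))
  }
  list(raster = phos_raster(values, geom), nodata = nodata, epsg = epsg)
}
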