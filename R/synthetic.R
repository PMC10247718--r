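#' Configuration of a synthetic world
#'
#' The generator builds an internally consistent miniature of the real
#' statistical system: provinces holding counties, 13 annual yearbook-style
#' tables, and matching rasters. Defaults mirror the real system's scale:
#' 31 provinces, 60-70 counties each (about two thousand counties), years
#' 2004-2016, four crop categories, sporadic missing county-years in runs
#' of at most two.
#'
#' Two flavors exist. In `"provincial_uniform"` worlds every county's true
#' rates equal its province's rates — the regime in which the allocation
#' scheme recovers county truth exactly. In `"heterogeneous"` worlds county
#' truth varies within provinces; allocation then conserves county totals
#' but cannot recover per-crop county truth (only province aggregates).
#'
#' @param n_provinces number of province-like units.
#' @param counties_per_province length-2 integer range (inclusive).
#' @param years inclusive integer range of years.
#' @param grid list with `nrow`, `ncol`, `px` (degrees) and `xmin`, `ymax`
#'   (upper-left corner, degrees).
#' @param missing_rate probability that a county-year's statistics are
#'   missing (0 <= rate < 1).
#' @param max_gap_run longest missing run the generator will leave in a
#'   county series.
#' @param flavor `"provincial_uniform"` or `"heterogeneous"`.
#' @param seed integer RNG seed; identical seed + config give a
#'   bit-identical world.
#' @return a `world_config` list.
#' @export
world_config <- function(n_provinces = 31L,
                         counties_per_province = c(60L, 70L),
                         years = 2004:2016,
                         grid = list(nrow = 92L, ncol = 92L, px = 0.01,
                                     xmin = 100, ymax = 40),
                         missing_rate = 0.05,
                         max_gap_run = 2L,
                         flavor = c("provincial_uniform", "heterogeneous"),
                         seed = 1L) {
  flavor <- match.arg(flavor)
  if (length(counties_per_province) == 1L) {
    counties_per_province <- rep(counties_per_province, 2L)
  }
  stopifnot(n_provinces >= 1L, counties_per_province[1] >= 1L,
            counties_per_province[2] >= counties_per_province[1],
            length(years) >= 1L, all(diff(years) == 1L),
            missing_rate >= 0, missing_rate < 1, max_gap_run >= 0L)
  structure(list(n_provinces = as.integer(n_provinces),
                 counties_per_province = as.integer(counties_per_province),
                 years = as.integer(years), grid = grid,
                 missing_rate = missing_rate,
                 max_gap_run = as.integer(max_gap_run),
                 flavor = flavor, seed = as.integer(seed)),
            class = "world_config")
}

# composition shares for arbitrary years: bundled table where available,
# nearest bundled year otherwise (keeps the generator self-contained)
.weights_for_years <- function(years) {
  w <- composition_weights()
  miss <- setdiff(years, w$year)
  if (length(miss)) {
    nearest <- vapply(miss, function(y) w$year[which.min(abs(w$year - y))],
                      integer(1))
    extra <- w[match(nearest, w$year), ]
    extra$year <- as.integer(miss)
    out <- rbind(as.data.frame(w), as.data.frame(extra))
    out <- out[order(out$year), ]
    attr(out, "content_imported") <- attr(w, "content_imported")
    attr(out, "content_domestic") <- attr(w, "content_domestic")
    class(out) <- class(w)
    rownames(out) <- NULL
    return(out)
  }
  w
}

#' Generate a complete synthetic world
#'
#' Draws provincial crop-specific rate trajectories (low-order polynomials
#' in year), county crop areas, and — in the heterogeneous flavor — county
#' rate multipliers, then derives every statistics table from that ground
#' truth so the tables are exactly consistent: county totals are the sum
#' of true crop consumptions, provincial totals are sums over counties,
#' and provincial rates are area-weighted means of county truth. Counties
#' are rectangular tiles on the grid; the county-ID raster assigns each
#' pixel to its tile, and each crop-year mask marks the pixels of counties
#' with positive growing area. Missing county-years are then blanked in
#' the observed county table, in runs no longer than `max_gap_run`.
#'
#' @param config a [world_config()].
#' @return a `phos_world` list: `config`, `truth` (county-year-crop truth
#'   rates and areas), `provincial_rates`, `provincial_totals`,
#'   `county_stats` (with NA gaps), `county_raster`, `crop_masks`
#'   (`[[crop]][[year]]`), `cropland_mask`, `weights`, `missing`
#'   (county-year missing pattern).
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  years <- config$years
  ny <- length(years)
  y0 <- years[1]
  np <- config$n_provinces
  rng <- config$counties_per_province
  n_per_prov <- if (rng[1] == rng[2]) rep(rng[1], np) else
    sample(rng[1]:rng[2], np, replace = TRUE)
  nc <- sum(n_per_prov)
  prov_ids <- sprintf("P%02d", seq_len(np))
  county_prov <- rep(prov_ids, n_per_prov)
  county_ids <- sprintf("C%04d", seq_len(nc))

  # --- county tiling on the grid -------------------------------------
  g <- config$grid
  ntx <- ceiling(sqrt(nc))
  nty <- ceiling(nc / ntx)
  th <- g$nrow %/% nty
  tw <- g$ncol %/% ntx
  if (th < 1L || tw < 1L) {
    stop("grid too small to host requested counties", call. = FALSE)
  }
  idx <- matrix(NA_integer_, g$nrow, g$ncol)
  for (ci in seq_len(nc)) {
    tr <- (ci - 1L) %/% ntx
    tc <- (ci - 1L) %% ntx
    idx[tr * th + seq_len(th), tc * tw + seq_len(tw)] <- ci
  }
  geom <- grid_geometry(g$nrow, g$ncol, g$xmin, g$ymax, g$px)
  county_raster <- phos_raster(idx, geom)
  attr(county_raster, "county_ids") <- county_ids

  # --- provincial rate trajectories ----------------------------------
  crops <- crop_categories()
  kinds <- fertilizer_kinds()
  pk <- expand.grid(province = prov_ids, crop = crops, kind = kinds,
                    stringsAsFactors = FALSE)
  lo <- ifelse(pk$kind == "phosphorus", 2, 3) *
    ifelse(pk$crop == "other", 0.5, 1)
  hi <- ifelse(pk$kind == "phosphorus", 8, 12) *
    ifelse(pk$crop == "other", 0.5, 1)
  pk$base <- runif(nrow(pk), lo, hi)
  pk$slope_rel <- runif(nrow(pk), -0.01, 0.03)
  pk$quad_rel <- runif(nrow(pk), -0.001, 0.001)
  prov_rate <- function(province, crop, kind, year) {
    i <- match(paste(province, crop, kind),
               paste(pk$province, pk$crop, pk$kind))
    t <- year - y0
    pk$base[i] * (1 + pk$slope_rel[i] * t + pk$quad_rel[i] * t^2)
  }

  # --- county areas ---------------------------------------------------
  tot_base <- runif(nc, 2e7, 2e8)
  pres <- matrix(runif(nc * 3) < 0.85, nc, 3)
  w <- matrix(runif(nc * 3, 0.1, 1), nc, 3) * pres
  named_frac <- runif(nc, 0.5, 0.8)
  wsum <- rowSums(w)
  any_named <- wsum > 0
  share <- w / ifelse(wsum > 0, wsum, 1) * named_frac * any_named
  A_base <- cbind(share * tot_base,
                  tot_base * (1 - named_frac * any_named))
  colnames(A_base) <- crops
  growth <- runif(nc, -0.005, 0.01)
  mcf <- runif(nc, 1.0, 1.8)      # multi-cropping factor
  het <- if (config$flavor == "heterogeneous") {
    matrix(runif(nc * 4, 0.7, 1.3), nc, 4, dimnames = list(NULL, crops))
  } else {
    matrix(1, nc, 4, dimnames = list(NULL, crops))
  }

  # --- ground-truth long table ---------------------------------------
  truth <- expand.grid(county = county_ids, year = years, crop = crops,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ci <- match(truth$county, county_ids)
  truth$province <- county_prov[ci]
  t_rel <- truth$year - y0
  truth$area <- A_base[cbind(ci, match(truth$crop, crops))] *
    (1 + growth[ci] * t_rel)
  truth$rate_phosphorus <- prov_rate(truth$province, truth$crop,
                                     "phosphorus", truth$year) *
    het[cbind(ci, match(truth$crop, crops))]
  truth$rate_component <- prov_rate(truth$province, truth$crop,
                                    "component", truth$year) *
    het[cbind(ci, match(truth$crop, crops))]
  weights <- .weights_for_years(years)
  content <- weighted_p2o5_content(truth$year, weights)
  truth$p2o5_rate <- truth$rate_phosphorus + truth$rate_component * content
  truth <- truth[order(truth$county, truth$year,
                       match(truth$crop, crops)),
                 c("county", "province", "year", "crop", "area",
                   "rate_phosphorus", "rate_component", "p2o5_rate")]
  rownames(truth) <- NULL

  # --- county statistics (from truth, fixed crop order) ---------------
  wide_area <- function(cr) truth$area[truth$crop == cr]
  base <- unique(truth[c("county", "province", "year")])
  cons_piece <- function(rate_col) {
    s <- 0
    for (cr in crops) {
      sub <- truth[truth$crop == cr, ]
      s <- s + sub[[rate_col]] * sub$area
    }
    s
  }
  a_r <- wide_area("rice"); a_w <- wide_area("wheat")
  a_m <- wide_area("maize"); a_o <- wide_area("other")
  county_stats <- data.frame(
    county = base$county, province = base$province, year = base$year,
    fc_phosphorus = cons_piece("rate_phosphorus"),
    fc_component = cons_piece("rate_component"),
    area_rice = a_r, area_wheat = a_w, area_maize = a_m,
    area_total = a_r + a_w + a_m + a_o,
    area_other = a_o,
    cropland_area = (a_r + a_w + a_m + a_o) / mcf[match(base$county,
                                                        county_ids)],
    stringsAsFactors = FALSE
  )
  rownames(county_stats) <- NULL

  # --- provincial tables: exact sums / area-weighted means -------------
  agg <- function(x, by) {
    r <- rowsum(x, group = by, reorder = TRUE)
    r[, 1]
  }
  pyk <- paste(county_stats$province, county_stats$year)
  prov_key <- sort(unique(pyk))
  split_py <- function(k) {
    parts <- strsplit(k, " ", fixed = TRUE)
    data.frame(province = vapply(parts, `[`, "", 1L),
               year = as.integer(vapply(parts, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  }
  pt <- split_py(prov_key)
  pt$consumption_phosphorus <- agg(county_stats$fc_phosphorus, pyk)
  pt$consumption_component <- agg(county_stats$fc_component, pyk)
  pt$area_rice <- agg(county_stats$area_rice, pyk)
  pt$area_wheat <- agg(county_stats$area_wheat, pyk)
  pt$area_maize <- agg(county_stats$area_maize, pyk)
  pt$area_total <- agg(county_stats$area_total, pyk)
  provincial_totals <- pt

  pr_list <- list()
  for (kind in kinds) {
    rate_col <- paste0("rate_", kind)
    for (cr in named_crops()) {
      sub <- truth[truth$crop == cr, ]
      k <- paste(sub$province, sub$year)
      num <- rowsum(sub[[rate_col]] * sub$area, k, reorder = TRUE)[, 1]
      den <- rowsum(sub$area, k, reorder = TRUE)[, 1]
      keys <- split_py(sort(unique(k)))
      keep <- den > 0
      pr_list[[length(pr_list) + 1L]] <- data.frame(
        province = keys$province[keep], year = keys$year[keep], crop = cr,
        kind = kind, rate = (num / den)[keep], stringsAsFactors = FALSE)
    }
  }
  provincial_rates <- do.call(rbind, pr_list)
  provincial_rates <- provincial_rates[order(provincial_rates$province,
                                             provincial_rates$year,
                                             provincial_rates$kind,
                                             match(provincial_rates$crop,
                                                   crops)), ]
  rownames(provincial_rates) <- NULL

  # --- missing county-years -------------------------------------------
  observed <- county_stats
  missing <- data.frame(county = character(0), year = integer(0))
  if (config$missing_rate > 0) {
    miss_mat <- matrix(runif(nc * ny) < config$missing_rate, nc, ny)
    for (ci2 in seq_len(nc)) {
      m <- miss_mat[ci2, ]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      for (j in seq_along(r$lengths)) {
        if (r$values[j] && r$lengths[j] > config$max_gap_run) {
          keep_from <- ends[j] - (r$lengths[j] - config$max_gap_run) + 1L
          m[keep_from:ends[j]] <- FALSE
        }
      }
      miss_mat[ci2, ] <- m
    }
    hit <- which(miss_mat, arr.ind = TRUE)
    if (nrow(hit)) {
      missing <- data.frame(county = county_ids[hit[, 1]],
                            year = years[hit[, 2]],
                            stringsAsFactors = FALSE)
      sel <- paste(observed$county, observed$year) %in%
        paste(missing$county, missing$year)
      blank <- c("fc_phosphorus", "fc_component", "area_rice", "area_wheat",
                 "area_maize", "area_total", "area_other")
      observed[sel, blank] <- NA_real_
    }
  }

  # --- masks -----------------------------------------------------------
  crop_masks <- list()
  for (cr in named_crops()) {
    pres_cy <- matrix(0L, nc, ny)
    sub <- truth[truth$crop == cr, ]
    pres_cy[cbind(match(sub$county, county_ids),
                  match(sub$year, years))] <- as.integer(sub$area > 0)
    crop_masks[[cr]] <- list()
    for (yi in seq_len(ny)) {
      mv <- matrix(0L, g$nrow, g$ncol)
      inside <- !is.na(idx)
      mv[inside] <- pres_cy[idx[inside], yi]
      crop_masks[[cr]][[as.character(years[yi])]] <- phos_raster(mv, geom)
    }
  }
  cropland_mask <- phos_raster(matrix(as.integer(!is.na(idx)), g$nrow,
                                      g$ncol), geom)

  structure(list(config = config, flavor = config$flavor, truth = truth,
                 provincial_rates = provincial_rates,
                 provincial_totals = provincial_totals,
                 county_stats = observed, county_raster = county_raster,
                 crop_masks = crop_masks, cropland_mask = cropland_mask,
                 weights = weights, missing = missing),
            class = "phos_world")
}

#' Inject a named pathology into a world
#'
#' Used to exercise the edge-case policies of the downstream stages:
#' `"overshoot_crops"` inflates one province-year's named-crop rates so
#' their implied consumption exceeds the provincial total (drives the
#' residual clamp); `"zero_area_county"` zeroes one county-year's areas
#' while keeping positive consumption (drives the undefined-ratio path);
#' `"long_gap"` blanks one county series for `max_gap_run + 2` consecutive
#' interior years (a run the gap-fill must refuse).
#'
#' @param world a `phos_world`.
#' @param inconsistency one of `"overshoot_crops"`, `"zero_area_county"`,
#'   `"long_gap"`.
#' @return the perturbed world; everything else unchanged.
#' @export
perturb_world <- function(world,
                          inconsistency = c("overshoot_crops",
                                            "zero_area_county",
                                            "long_gap")) {
  stopifnot(inherits(world, "phos_world"))
  inconsistency <- match.arg(inconsistency)
  w <- world
  if (inconsistency == "overshoot_crops") {
    pt <- w$provincial_totals[1, ]
    sel <- w$provincial_rates$province == pt$province &
      w$provincial_rates$year == pt$year &
      w$provincial_rates$kind == "phosphorus"
    named_area <- pt$area_rice + pt$area_wheat + pt$area_maize
    # scale so the named crops alone consume 1.5x the provincial total
    cur <- sum(w$provincial_rates$rate[sel] *
                 unlist(pt[paste0("area_",
                                  w$provincial_rates$crop[sel])]))
    if (cur <= 0) stop("cannot construct overshoot on a zero-rate province",
                       call. = FALSE)
    w$provincial_rates$rate[sel] <- w$provincial_rates$rate[sel] *
      1.5 * pt$consumption_phosphorus / cur
  } else if (inconsistency == "zero_area_county") {
    i <- which(!is.na(w$county_stats$fc_phosphorus) &
                 w$county_stats$fc_phosphorus > 0)[1]
    if (is.na(i)) stop("no county-year with positive consumption",
                       call. = FALSE)
    w$county_stats[i, c("area_rice", "area_wheat", "area_maize",
                        "area_total", "area_other")] <- 0
  } else {
    run <- w$config$max_gap_run + 2L
    years <- w$config$years
    if (length(years) < run + 2L) {
      stop("too few years to host an interior long gap", call. = FALSE)
    }
    cty <- w$county_stats$county[1]
    gap_years <- years[2:(1L + run)]
    sel <- w$county_stats$county == cty & w$county_stats$year %in% gap_years
    blank <- c("fc_phosphorus", "fc_component", "area_rice", "area_wheat",
               "area_maize", "area_total", "area_other")
    w$county_stats[sel, blank] <- NA_real_
  }
  w
}
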