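#' Read the tabular statistics that feed the pipeline
#'
#' Reads the three input CSV files (UTF-8, header row, RFC-4180) and returns
#' the canonical-unit tables. The files use a long interchange schema, one
#' value per row, because the source yearbook layouts vary:
#'
#' * `provincial_rates`: columns `province,year,crop,kind,rate` — one
#'   crop-specific rate per province-year-kind (named crops only).
#' * `provincial_totals`: columns `province,year,crop,kind,variable,value`
#'   with `variable` `"consumption"` (kind set, crop empty) or `"area"`
#'   (crop one of rice/wheat/maize/total, kind empty).
#' * `county_stats`: columns `county,province,year,crop,kind,variable,value`
#'   with `variable` `"consumption"`, `"area"` or `"cropland"`. An empty
#'   `value` cell (or an absent row) is an explicitly missing statistic and
#'   is kept as NA — never silently zero.
#'
#' `units` names the units the files are expressed in; values are converted
#' to the canonical grams / square metres / g per m^2 on read.
#'
#' @param paths named list or character vector with elements
#'   `provincial_rates`, `provincial_totals`, `county_stats`.
#' @param units named list with elements `rate`, `mass`, `area`; see
#'   [convert_unit()] for the recognized labels.
#' @return list with elements `provincial_rates`, `provincial_totals`,
#'   `county_stats` (validated data frames in canonical units).
#' @export
read_statistics <- function(paths,
                            units = list(rate = "g_per_m2", mass = "g",
                                         area = "m2")) {
  need <- c("provincial_rates", "provincial_totals", "county_stats")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("paths is missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  for (u in c("rate", "mass", "area")) {
    if (is.null(units[[u]])) stop("units$", u, " not given", call. = FALSE)
  }

  pr <- .read_long(paths[["provincial_rates"]])
  .check_cols(pr, c("province", "year", "crop", "kind", "rate"),
              "provincial_rates file")
  pr$rate <- convert_unit(as.numeric(pr$rate), units$rate, "rate")
  pr <- pr[c("province", "year", "crop", "kind", "rate")]
  validate_provincial_rates(pr)

  pt_long <- .read_long(paths[["provincial_totals"]])
  .check_cols(pt_long, c("province", "year", "crop", "kind", "variable",
                         "value"), "provincial_totals file")
  pt <- .pivot_totals(pt_long, units, id = "province")
  validate_provincial_totals(pt)

  ct_long <- .read_long(paths[["county_stats"]])
  .check_cols(ct_long, c("county", "province", "year", "crop", "kind",
                         "variable", "value"), "county_stats file")
  ct <- .pivot_county(ct_long, units)
  unknown <- setdiff(unique(ct$province), unique(pt$province))
  if (length(unknown)) {
    stop("county statistics reference unknown province(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  validate_county_stats(ct)

  list(provincial_rates = pr, provincial_totals = pt, county_stats = ct)
}

.read_long <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 colClasses = "character", fileEncoding = "UTF-8")
  if ("year" %in% names(df)) df$year <- as.integer(df$year)
  df
}

# long (province,year,crop,kind,variable,value) -> wide provincial totals
.pivot_totals <- function(long, units, id = "province") {
  long$value <- as.numeric(long$value)
  cons <- long[long$variable == "consumption", ]
  .check_unique_key(cons, c(id, "year", "kind"), "provincial consumption rows")
  area <- long[long$variable == "area", ]
  .check_unique_key(area, c(id, "year", "crop"), "provincial area rows")

  key <- unique(long[c(id, "year")])
  key <- key[order(key[[id]], key$year), , drop = FALSE]
  pick <- function(df, keep, col, val) {
    sub <- df[df[[col]] == val, ]
    i <- match(paste(key[[id]], key$year),
               paste(sub[[id]], sub$year))
    sub$value[i]
  }
  out <- data.frame(
    province = key[[id]], year = key$year,
    consumption_phosphorus = convert_unit(pick(cons, key, "kind", "phosphorus"),
                                          units$mass, "mass"),
    consumption_component = convert_unit(pick(cons, key, "kind", "component"),
                                         units$mass, "mass"),
    area_rice = convert_unit(pick(area, key, "crop", "rice"), units$area, "area"),
    area_wheat = convert_unit(pick(area, key, "crop", "wheat"), units$area, "area"),
    area_maize = convert_unit(pick(area, key, "crop", "maize"), units$area, "area"),
    area_total = convert_unit(pick(area, key, "crop", "total"), units$area, "area"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

.pivot_county <- function(long, units) {
  long$value <- as.numeric(long$value)
  cons <- long[long$variable == "consumption", ]
  .check_unique_key(cons, c("county", "year", "kind"), "county consumption rows")
  area <- long[long$variable == "area", ]
  .check_unique_key(area, c("county", "year", "crop"), "county area rows")
  crop_land <- long[long$variable == "cropland", ]
  .check_unique_key(crop_land, c("county", "year"), "county cropland rows")

  key <- unique(long[c("county", "province", "year")])
  if (anyDuplicated(key[c("county", "year")])) {
    stop("county mapped to more than one province in county_stats file",
         call. = FALSE)
  }
  key <- key[order(key$county, key$year), , drop = FALSE]
  k <- paste(key$county, key$year)
  pick <- function(df, col, val) {
    sub <- if (is.null(col)) df else df[df[[col]] == val, ]
    sub$value[match(k, paste(sub$county, sub$year))]
  }
  out <- data.frame(
    county = key$county, province = key$province, year = key$year,
    fc_phosphorus = convert_unit(pick(cons, "kind", "phosphorus"), units$mass, "mass"),
    fc_component = convert_unit(pick(cons, "kind", "component"), units$mass, "mass"),
    area_rice = convert_unit(pick(area, "crop", "rice"), units$area, "area"),
    area_wheat = convert_unit(pick(area, "crop", "wheat"), units$area, "area"),
    area_maize = convert_unit(pick(area, "crop", "maize"), units$area, "area"),
    area_total = convert_unit(pick(area, "crop", "total"), units$area, "area"),
    cropland_area = convert_unit(pick(crop_land, NULL, NULL), units$area, "area"),
    stringsAsFactors = FALSE
  )
  out$area_other <- other_area(out$area_total, out$area_rice, out$area_wheat,
                               out$area_maize)
  rownames(out) <- NULL
  out
}

# full-precision numeric formatting so that write -> read is bit-exact
.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write and re-read a county rate table
#'
#' The on-disk form is a long CSV, one row per county-year-crop-kind plus
#' one for the combined P2O5 rate, with the provenance flag alongside each
#' value. Numbers are written with 17 significant digits so a write/read
#' round trip reproduces the table bit-exactly, flags included.
#'
#' @param df a validated county rate table (see [validate_county_rates()]).
#' @param path output CSV path.
#' @return `write_county_rates()` returns `path` invisibly;
#'   `read_county_rates()` returns the table.
#' @export
write_county_rates <- function(df, path) {
  validate_county_rates(df)
  has_p2o5 <- "p2o5_rate" %in% names(df)
  piece <- function(kind_lab, val, flag) {
    data.frame(county = df$county, province = df$province, year = df$year,
               crop = df$crop, kind = kind_lab, rate = .fmt_num(val),
               flag = flag, stringsAsFactors = FALSE)
  }
  long <- rbind(
    piece("phosphorus", df$rate_phosphorus, df$flag_phosphorus),
    piece("component", df$rate_component, df$flag_component),
    if (has_p2o5) piece("p2o5", df$p2o5_rate, df$flag_p2o5)
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(long, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_county_rates
#' @export
read_county_rates <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = NULL, fileEncoding = "UTF-8")
  long$year <- as.integer(long$year)
  long$value <- ifelse(long$rate == "", NA_real_, as.numeric(long$rate))
  base <- unique(long[c("county", "province", "year", "crop")])
  base <- base[order(base$county, base$year,
                     match(base$crop, crop_categories())), , drop = FALSE]
  k <- paste(base$county, base$year, base$crop)
  pick <- function(kind_lab, what) {
    sub <- long[long$kind == kind_lab, ]
    sub[[what]][match(k, paste(sub$county, sub$year, sub$crop))]
  }
  out <- data.frame(
    county = base$county, province = base$province, year = base$year,
    crop = base$crop,
    rate_phosphorus = pick("phosphorus", "value"),
    flag_phosphorus = pick("phosphorus", "flag"),
    rate_component = pick("component", "value"),
    flag_component = pick("component", "flag"),
    stringsAsFactors = FALSE
  )
  if (any(long$kind == "p2o5")) {
    out$p2o5_rate <- pick("p2o5", "value")
    out$flag_p2o5 <- pick("p2o5", "flag")
  }
  rownames(out) <- NULL
  validate_county_rates(out)
  out
}

#' Write a synthetic world's statistics tables as input CSVs
#'
#' Emits the three statistics files in the interchange schema accepted by
#' [read_statistics()], in canonical units (`g_per_m2`, `g`, `m2`), so a
#' generated world can be round-tripped through the file interface.
#'
#' @param world a world from [generate_world()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_world_csv <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- world$provincial_rates
  pr$rate <- .fmt_num(pr$rate)
  p_rates <- file.path(dir, "provincial_rates.csv")
  write.csv(pr, p_rates, row.names = FALSE, na = "")

  pt <- world$provincial_totals
  long_pt <- rbind(
    data.frame(province = pt$province, year = pt$year, crop = "",
               kind = "phosphorus", variable = "consumption",
               value = .fmt_num(pt$consumption_phosphorus)),
    data.frame(province = pt$province, year = pt$year, crop = "",
               kind = "component", variable = "consumption",
               value = .fmt_num(pt$consumption_component)),
    do.call(rbind, lapply(c("rice", "wheat", "maize", "total"), function(cr) {
      data.frame(province = pt$province, year = pt$year, crop = cr,
                 kind = "", variable = "area",
                 value = .fmt_num(pt[[paste0("area_", cr)]]))
    }))
  )
  p_totals <- file.path(dir, "provincial_totals.csv")
  write.csv(long_pt, p_totals, row.names = FALSE, na = "")

  ct <- world$county_stats
  long_ct <- rbind(
    data.frame(county = ct$county, province = ct$province, year = ct$year,
               crop = "", kind = "phosphorus", variable = "consumption",
               value = .fmt_num(ct$fc_phosphorus)),
    data.frame(county = ct$county, province = ct$province, year = ct$year,
               crop = "", kind = "component", variable = "consumption",
               value = .fmt_num(ct$fc_component)),
    do.call(rbind, lapply(c("rice", "wheat", "maize", "total"), function(cr) {
      data.frame(county = ct$county, province = ct$province, year = ct$year,
                 crop = cr, kind = "", variable = "area",
                 value = .fmt_num(ct[[paste0("area_", cr)]]))
    })),
    data.frame(county = ct$county, province = ct$province, year = ct$year,
               crop = "", kind = "", variable = "cropland",
               value = .fmt_num(ct$cropland_area))
  )
  p_county <- file.path(dir, "county_stats.csv")
  write.csv(long_ct, p_county, row.names = FALSE, na = "")

  invisible(c(provincial_rates = p_rates, provincial_totals = p_totals,
              county_stats = p_county))
}
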