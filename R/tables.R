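#' Crop categories and fertilizer kinds
#'
#' The pipeline works with four crop categories — the three mapped staple
#' crops plus a residual `"other"` category covering everything else — and
#' two fertilizer kinds: straight phosphorus fertilizer (whose statistics
#' are already P2O5 mass) and multi-nutrient compound ("component")
#' fertilizer, whose P2O5 contribution requires a content conversion.
#'
#' @return character vectors of level names, in the fixed enumeration order
#'   used for all deterministic summations.
#' @export
crop_categories <- function() c("rice", "wheat", "maize", "other")

#' @rdname crop_categories
#' @export
named_crops <- function() c("rice", "wheat", "maize")

#' @rdname crop_categories
#' @export
fertilizer_kinds <- function() c("phosphorus", "component")

# flags shared by all provenance-carrying tables
.flag_levels <- c("observed", "derived", "gap_filled", "clamped",
                  "undefined", "missing", "partial", "no_other_rate",
                  "dropped")

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

.check_unique_key <- function(df, key, what) {
  if (anyDuplicated(df[key])) {
    stop("duplicate key rows in ", what, " (key: ",
         paste(key, collapse = ", "), ")", call. = FALSE)
  }
}

#' Validate a provincial crop-specific rate table
#'
#' Rates are crop-specific fertilizer application rates per province-year
#' and kind, in g/m^2. On input only the named crops are present; after
#' [other_crops_rate()] the residual `"other"` category is appended with a
#' provenance flag.
#'
#' @param df data frame with columns `province`, `year`, `crop`, `kind`,
#'   `rate` (and optionally `flag`).
#' @param allow_other permit the `"other"` category (post provincial stage).
#' @return `df`, invisibly, after validation.
#' @export
validate_provincial_rates <- function(df, allow_other = FALSE) {
  .check_cols(df, c("province", "year", "crop", "kind", "rate"),
              "provincial rate table")
  crops <- if (allow_other) crop_categories() else named_crops()
  bad <- setdiff(unique(df$crop), crops)
  if (length(bad)) stop("unknown crop categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(df$kind), fertilizer_kinds())
  if (length(bad)) stop("unknown fertilizer kinds: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(df$rate < 0, na.rm = TRUE)) stop("negative rate in provincial rate table",
                                           call. = FALSE)
  .check_unique_key(df, c("province", "year", "crop", "kind"),
                    "provincial rate table")
  invisible(df)
}

#' Validate a provincial totals table
#'
#' One row per province-year holding total phosphorus/component fertilizer
#' consumption (g) and the crop-specific and total sown areas (m^2). The
#' residual other-crops area is the total minus the named crops and must be
#' non-negative.
#'
#' @param df data frame with columns `province`, `year`,
#'   `consumption_phosphorus`, `consumption_component`, `area_rice`,
#'   `area_wheat`, `area_maize`, `area_total`.
#' @return `df`, invisibly.
#' @export
validate_provincial_totals <- function(df) {
  .check_cols(df, c("province", "year", "consumption_phosphorus",
                    "consumption_component", "area_rice", "area_wheat",
                    "area_maize", "area_total"), "provincial totals table")
  .check_unique_key(df, c("province", "year"), "provincial totals table")
  num <- c("consumption_phosphorus", "consumption_component",
           "area_rice", "area_wheat", "area_maize", "area_total")
  if (any(unlist(df[num]) < 0, na.rm = TRUE)) {
    stop("negative consumption or area in provincial totals", call. = FALSE)
  }
  named <- df$area_rice + df$area_wheat + df$area_maize
  over <- !is.na(named) & !is.na(df$area_total) &
    named > df$area_total * (1 + 1e-9)
  if (any(over)) {
    stop("named-crop areas exceed total sown area for ",
         sum(over), " province-year row(s)", call. = FALSE)
  }
  invisible(df)
}

#' Validate a county statistics table
#'
#' One row per county-year with total fertilizer consumption per kind (g),
#' named-crop and total sown areas (m^2), the derived residual other-crops
#' area, and physical cropland area. Missing county-year statistics are NA
#' (an explicit missing state, never zero); provenance columns `<col>_src`
#' are added by [gap_fill_county()].
#'
#' @param df data frame with columns `county`, `province`, `year`,
#'   `fc_phosphorus`, `fc_component`, `area_rice`, `area_wheat`,
#'   `area_maize`, `area_total`, `area_other`, `cropland_area`.
#' @return `df`, invisibly.
#' @export
validate_county_stats <- function(df) {
  .check_cols(df, c("county", "province", "year", "fc_phosphorus",
                    "fc_component", "area_rice", "area_wheat", "area_maize",
                    "area_total", "area_other", "cropland_area"),
              "county statistics table")
  .check_unique_key(df, c("county", "year"), "county statistics table")
  map <- unique(df[c("county", "province")])
  if (anyDuplicated(map$county)) {
    stop("county mapped to more than one province: ",
         paste(map$county[duplicated(map$county)], collapse = ", "),
         call. = FALSE)
  }
  num <- c("fc_phosphorus", "fc_component", "area_rice", "area_wheat",
           "area_maize", "area_total", "area_other", "cropland_area")
  if (any(unlist(df[num]) < 0, na.rm = TRUE)) {
    stop("negative value in county statistics", call. = FALSE)
  }
  invisible(df)
}

#' Residual other-crops sown area
#'
#' Total sown area minus the named crops, floored at zero. NA if any input
#' is missing.
#'
#' @param area_total,area_rice,area_wheat,area_maize areas in m^2.
#' @return numeric vector of other-crops areas (m^2).
#' @export
other_area <- function(area_total, area_rice, area_wheat, area_maize) {
  pmax(0, area_total - area_rice - area_wheat - area_maize)
}

#' Validate a county rate table
#'
#' Harmonized county crop-specific rates: one row per county-year-crop with
#' per-kind rates (g/m^2), the combined P2O5 rate (g P2O5 m^-2), and a
#' provenance flag per value.
#'
#' @param df data frame with columns `county`, `province`, `year`, `crop`,
#'   `rate_phosphorus`, `flag_phosphorus`, `rate_component`,
#'   `flag_component`, and optionally `p2o5_rate`, `flag_p2o5`.
#' @return `df`, invisibly.
#' @export
validate_county_rates <- function(df) {
  .check_cols(df, c("county", "province", "year", "crop", "rate_phosphorus",
                    "flag_phosphorus", "rate_component", "flag_component"),
              "county rate table")
  .check_unique_key(df, c("county", "year", "crop"), "county rate table")
  flags <- c(df$flag_phosphorus, df$flag_component,
             if ("flag_p2o5" %in% names(df)) df$flag_p2o5)
  bad <- setdiff(unique(flags), .flag_levels)
  if (length(bad)) stop("unknown provenance flag(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if ("p2o5_rate" %in% names(df) &&
      any(df$p2o5_rate < 0, na.rm = TRUE)) {
    stop("negative P2O5 rate in county rate table", call. = FALSE)
  }
  invisible(df)
}
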