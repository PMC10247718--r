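#' Composition of compound ("component") fertilizer by year
#'
#' Component fertilizer sold in a given year is a mix of imported and
#' domestically produced product with very different P2O5 mass fractions
#' (60.0% imported vs 30.8% domestic). The bundled constants file carries
#' the national import/domestic shares for 2004-2016; supply another CSV
#' (columns `year,imported_pct,domestic_pct`, shares in percent) for other
#' countries or periods.
#'
#' @param path CSV of shares in percent; defaults to the bundled table.
#' @param content_imported,content_domestic P2O5 mass fractions of imported
#'   and domestic product (overridable).
#' @return data frame with columns `year`, `imported_share`,
#'   `domestic_share` (fractions) and attributes `content_imported`,
#'   `content_domestic`.
#' @export
composition_weights <- function(path = NULL,
                                content_imported = 0.600,
                                content_domestic = 0.308) {
  if (is.null(path)) {
    path <- system.file("extdata", "component_composition.csv",
                        package = "phosgrid", mustWork = TRUE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  .check_cols(raw, c("year", "imported_pct", "domestic_pct"),
              "composition constants file")
  s <- raw$imported_pct + raw$domestic_pct
  if (any(abs(s - 100) > 0.1)) {
    stop("import/domestic shares do not sum to 100% (within 0.1 pp) for year(s): ",
         paste(raw$year[abs(s - 100) > 0.1], collapse = ", "), call. = FALSE)
  }
  if (any(raw$imported_pct < 0 | raw$imported_pct > 100 |
          raw$domestic_pct < 0 | raw$domestic_pct > 100)) {
    stop("shares must lie in [0, 100]%", call. = FALSE)
  }
  stopifnot(content_imported >= 0, content_imported <= 1,
            content_domestic >= 0, content_domestic <= 1)
  out <- data.frame(year = as.integer(raw$year),
                    imported_share = raw$imported_pct / 100,
                    domestic_share = raw$domestic_pct / 100)
  attr(out, "content_imported") <- content_imported
  attr(out, "content_domestic") <- content_domestic
  class(out) <- c("composition_weights", class(out))
  out
}

#' Weighted P2O5 content of component fertilizer in a year
#'
#' `imported_share * content_imported + domestic_share * content_domestic`,
#' a mass fraction strictly between the domestic and imported contents
#' whenever both shares are non-zero.
#'
#' @param year integer year(s); must be present in `weights`.
#' @param weights a [composition_weights()] table.
#' @return numeric vector of P2O5 mass fractions.
#' @examples
#' w <- composition_weights()
#' weighted_p2o5_content(2004, w)  # 0.41312
#' @export
weighted_p2o5_content <- function(year, weights) {
  i <- match(year, weights$year)
  if (anyNA(i)) {
    stop("no composition shares for year(s): ",
         paste(unique(year[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  weights$imported_share[i] * attr(weights, "content_imported") +
    weights$domestic_share[i] * attr(weights, "content_domestic")
}

#' Convert component-fertilizer mass to P2O5 mass
#'
#' Multiplies gross product mass by that year's weighted P2O5 content.
#' Linear in the amount.
#'
#' @param amount grams of component fertilizer (>= 0).
#' @param year integer year(s).
#' @param weights a [composition_weights()] table.
#' @return grams of P2O5.
#' @export
component_to_p2o5 <- function(amount, year, weights) {
  if (any(amount < 0, na.rm = TRUE)) {
    stop("component fertilizer amount must be non-negative", call. = FALSE)
  }
  amount * weighted_p2o5_content(year, weights)
}

#' Convert elemental phosphorus mass to P2O5 mass
#'
#' P2O5 has molar mass 142 g/mol and contains two P atoms (62 g), so
#' 1 g P corresponds to 142/62 g P2O5. Used when comparing against
#' datasets reported in elemental P.
#'
#' @param amount grams of elemental P (>= 0).
#' @return grams of P2O5.
#' @examples
#' p_mass_to_p2o5(62)  # 142
#' @export
p_mass_to_p2o5 <- function(amount) {
  if (any(amount < 0, na.rm = TRUE)) {
    stop("phosphorus mass must be non-negative", call. = FALSE)
  }
  amount * 142 / 62
}

#' Combined P2O5 rate from the two fertilizer kinds
#'
#' Phosphorus-fertilizer statistics are already P2O5 mass, so the combined
#' rate is the phosphorus-kind rate plus the component-kind rate scaled by
#' that year's weighted P2O5 content. If one kind is missing for a record
#' the sum runs over the available kind and the record is flagged
#' `"partial"`; if both are missing the P2O5 rate is NA, flagged
#' `"missing"`.
#'
#' @param county_rates a county rate table with per-kind rates (see
#'   [county_rates()]).
#' @param weights a [composition_weights()] table.
#' @return the table with `p2o5_rate` and `flag_p2o5` columns added.
#' @export
total_p2o5_rate <- function(county_rates, weights) {
  validate_county_rates(county_rates)
  content <- weighted_p2o5_content(county_rates$year, weights)
  p <- county_rates$rate_phosphorus
  k <- county_rates$rate_component * content
  both <- !is.na(p) & !is.na(k)
  one <- xor(is.na(p), is.na(k))
  out <- county_rates
  out$p2o5_rate <- ifelse(both, p + k, ifelse(is.na(p), k, p))
  filled <- county_rates$flag_phosphorus == "gap_filled" |
    county_rates$flag_component == "gap_filled"
  out$flag_p2o5 <- ifelse(!both & !one, "missing",
                          ifelse(one, "partial",
                                 ifelse(filled, "gap_filled", "derived")))
  # per-kind undefined (zero-area) records stay undefined for the sum too
  undef <- county_rates$flag_phosphorus == "undefined" &
    county_rates$flag_component == "undefined"
  out$p2o5_rate[undef] <- NA_real_
  out$flag_p2o5[undef] <- "undefined"
  out
}
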