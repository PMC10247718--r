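# builds the 3-province / 6-county input CSV fixture in yearbook-style
# units (kg/ha, t, thousand hectares); returns the file paths
make_fixture_csvs <- function(dir, blank_cell = TRUE) {
  provs <- c("PA", "PB", "PC")
  years <- 2004:2005
  pr <- expand.grid(province = provs, year = years, crop = named_crops(),
                    kind = fertilizer_kinds(), stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  pr$rate <- 65  # kg/ha
  p_rates <- file.path(dir, "provincial_rates.csv")
  write.csv(pr[c("province", "year", "crop", "kind", "rate")], p_rates,
            row.names = FALSE)

  pt_cons <- expand.grid(province = provs, year = years,
                         kind = fertilizer_kinds(), stringsAsFactors = FALSE)
  pt_cons$crop <- ""
  pt_cons$variable <- "consumption"
  pt_cons$value <- 100  # t
  pt_area <- expand.grid(province = provs, year = years,
                         crop = c("rice", "wheat", "maize", "total"),
                         stringsAsFactors = FALSE)
  pt_area$kind <- ""
  pt_area$variable <- "area"
  pt_area$value <- ifelse(pt_area$crop == "total", 50, 10)  # khm2
  cols <- c("province", "year", "crop", "kind", "variable", "value")
  p_totals <- file.path(dir, "provincial_totals.csv")
  write.csv(rbind(pt_cons[cols], pt_area[cols]), p_totals, row.names = FALSE)

  counties <- sprintf("K%d", 1:6)
  cmap <- rep(provs, each = 2)
  ct_cons <- expand.grid(county = counties, year = years,
                         kind = fertilizer_kinds(), stringsAsFactors = FALSE)
  ct_cons$province <- cmap[match(ct_cons$county, counties)]
  ct_cons$crop <- ""
  ct_cons$variable <- "consumption"
  ct_cons$value <- "5"
  if (blank_cell) {
    ct_cons$value[ct_cons$county == "K1" & ct_cons$year == 2004 &
                    ct_cons$kind == "phosphorus"] <- ""
  }
  ct_area <- expand.grid(county = counties, year = years,
                         crop = c("rice", "wheat", "maize", "total"),
                         stringsAsFactors = FALSE)
  ct_area$province <- cmap[match(ct_area$county, counties)]
  ct_area$kind <- ""
  ct_area$variable <- "area"
  ct_area$value <- ifelse(ct_area$crop == "total", "5", "1")
  ct_land <- expand.grid(county = counties, year = years,
                         stringsAsFactors = FALSE)
  ct_land$province <- cmap[match(ct_land$county, counties)]
  ct_land$crop <- ""
  ct_land$kind <- ""
  ct_land$variable <- "cropland"
  ct_land$value <- "4"
  cols <- c("county", "province", "year", "crop", "kind", "variable", "value")
  p_county <- file.path(dir, "county_stats.csv")
  write.csv(rbind(ct_cons[cols], ct_area[cols], ct_land[cols]), p_county,
            row.names = FALSE)

  c(provincial_rates = p_rates, provincial_totals = p_totals,
    county_stats = p_county)
}

fixture_units <- list(rate = "kg_per_ha", mass = "t", area = "khm2")

# seeded random county rate table with all flag states represented
random_rate_table <- function(n = 1000, seed = 99) {
  set.seed(seed)
  counties <- sprintf("C%04d", 1:50)
  df <- expand.grid(county = counties, year = 2004:2016,
                    crop = crop_categories(), stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  df <- df[sample.int(nrow(df), n), ]
  df$province <- sprintf("P%02d", 1 + (match(df$county, counties) - 1) %/% 10)
  df$rate_phosphorus <- runif(n, 0, 10)
  df$flag_phosphorus <- sample(c("derived", "gap_filled", "clamped"), n,
                               replace = TRUE)
  df$rate_component <- runif(n, 0, 10)
  df$flag_component <- sample(c("derived", "gap_filled"), n, replace = TRUE)
  undef <- sample.int(n, 20)
  df$rate_phosphorus[undef] <- NA_real_
  df$flag_phosphorus[undef] <- "undefined"
  df$p2o5_rate <- df$rate_phosphorus + 0.4 * df$rate_component
  df$flag_p2o5 <- ifelse(is.na(df$p2o5_rate), "partial", "derived")
  df$p2o5_rate[is.na(df$p2o5_rate)] <- df$rate_component[is.na(df$p2o5_rate)]
  df <- df[order(df$county, df$year, match(df$crop, crop_categories())),
           c("county", "province", "year", "crop", "rate_phosphorus",
             "flag_phosphorus", "rate_component", "flag_component",
             "p2o5_rate", "flag_p2o5")]
  rownames(df) <- NULL
  df
}
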