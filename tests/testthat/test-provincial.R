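# minimal one-province tables for hand-built scenarios
prov_tables <- function(rates_gm2, areas_m2, total_g, area_total_m2,
                        kind = "phosphorus") {
  rates <- data.frame(province = "P1", year = 2004L, crop = named_crops(),
                      kind = kind, rate = rates_gm2, stringsAsFactors = FALSE)
  totals <- data.frame(province = "P1", year = 2004L,
                       consumption_phosphorus = ifelse(kind == "phosphorus",
                                                       total_g, 0),
                       consumption_component = ifelse(kind == "component",
                                                      total_g, 0),
                       area_rice = areas_m2[1], area_wheat = areas_m2[2],
                       area_maize = areas_m2[3], area_total = area_total_m2,
                       stringsAsFactors = FALSE)
  list(rates = rates, totals = totals)
}

test_that("crop consumption is rate times area", {
  tb <- prov_tables(c(8.7, 0, 1), c(1e6, 1e6, 1e6), 1e8, 4e6)
  cons <- crop_consumption(tb$rates, tb$totals)
  expect_equal(cons$consumption[cons$crop == "rice"], 8.7e6)
  expect_equal(cons$consumption[cons$crop == "wheat"], 0)

  # independent spreadsheet-style oracle on a 2-province, 3-crop fixture
  set.seed(21)
  rates <- expand.grid(province = c("PA", "PB"), year = 2004L,
                       crop = named_crops(), kind = "phosphorus",
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rates$rate <- runif(6, 1, 10)
  totals <- data.frame(province = c("PA", "PB"), year = 2004L,
                       consumption_phosphorus = 1e9,
                       consumption_component = 1e9,
                       area_rice = c(1e6, 2e6), area_wheat = c(3e6, 4e6),
                       area_maize = c(5e6, 6e6), area_total = 2e7)
  cons <- crop_consumption(rates, totals)
  expect_equal(nrow(cons), 6)
  for (r in seq_len(nrow(cons))) {
    a <- totals[totals$province == cons$province[r],
                paste0("area_", cons$crop[r])]
    rt <- rates$rate[rates$province == cons$province[r] &
                       rates$crop == cons$crop[r]]
    expect_identical(cons$consumption[r], rt * a)
  }

  # a rate without a matching totals row is an error
  bad <- rates
  bad$province[1] <- "PZ"
  expect_error(crop_consumption(bad, totals), "no totals row")
})

test_that("other-crops rate is the residual over the residual area", {
  # named crops consume 60 g of the 100 g total; other area 20 m2 -> 2 g/m2
  tb <- prov_tables(c(6, 0, 0), c(10, 0, 0), 100, 30)
  st <- provincial_stage(tb$rates, tb$totals)
  oth <- st$rates[st$rates$crop == "other", ]
  expect_equal(oth$rate[oth$kind == "phosphorus"], (100 - 60) / 20)
  expect_equal(oth$flag[oth$kind == "phosphorus"], "derived")

  # named consumption above the total: clamped to zero, flagged
  tb <- prov_tables(c(11, 0, 0), c(10, 0, 0), 100, 30)
  st <- provincial_stage(tb$rates, tb$totals)
  oth <- st$rates[st$rates$crop == "other" & st$rates$kind == "phosphorus", ]
  expect_equal(oth$rate, 0)
  expect_equal(oth$flag, "clamped")

  # zero other area with a positive residual: undefined, no rate
  tb <- prov_tables(c(6, 0, 0), c(10, 0, 0), 100, 10)
  st <- provincial_stage(tb$rates, tb$totals)
  oth <- st$rates[st$rates$crop == "other" & st$rates$kind == "phosphorus", ]
  expect_true(is.na(oth$rate))
  expect_equal(oth$flag, "undefined")
})

test_that("unclamped provincial consumption conserves the total", {
  w <- tiny_world(seed = 12, flavor = "heterogeneous")
  st <- provincial_stage(w$provincial_rates, w$provincial_totals)
  cons <- st$consumption
  k <- paste(cons$province, cons$year, cons$kind)
  s <- tapply(cons$consumption, k, sum)
  pt <- w$provincial_totals
  want <- c(setNames(pt$consumption_phosphorus,
                     paste(pt$province, pt$year, "phosphorus")),
            setNames(pt$consumption_component,
                     paste(pt$province, pt$year, "component")))
  expect_lt(max_rel_err(as.numeric(s), as.numeric(want[names(s)])), 1e-9)
})

test_that("the residual rate is homogeneous of degree one", {
  tb <- prov_tables(c(3, 4, 5), c(1e5, 2e5, 3e5), 5e6, 1e6)
  base <- provincial_stage(tb$rates, tb$totals)$rates
  c0 <- 3.7
  tb$rates$rate <- tb$rates$rate * c0
  tb$totals$consumption_phosphorus <- tb$totals$consumption_phosphorus * c0
  scaled <- provincial_stage(tb$rates, tb$totals)$rates
  oth <- base$crop == "other" & base$kind == "phosphorus"
  expect_equal(scaled$rate[oth], c0 * base$rate[oth], tolerance = 1e-12)
})

test_that("the provincial stage recovers generator truth on a clean world", {
  w <- tiny_world(seed = 13)
  st <- provincial_stage(w$provincial_rates, w$provincial_totals)
  oth <- st$rates[st$rates$crop == "other", ]
  tr <- w$truth[w$truth$crop == "other", ]
  for (kind in fertilizer_kinds()) {
    o <- oth[oth$kind == kind, ]
    want <- tr[[paste0("rate_", kind)]][match(paste(o$province, o$year),
                                              paste(tr$province, tr$year))]
    expect_lt(max_rel_err(o$rate, want), 1e-9)
  }
})
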