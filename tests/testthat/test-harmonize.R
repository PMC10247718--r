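# one-county scaffolding for hand-built allocation scenarios
one_county <- function(areas, fc = c(phosphorus = 1000, component = 0),
                       prov_rates = NULL) {
  cs <- data.frame(county = "C1", province = "P1", year = 2004L,
                   fc_phosphorus = fc[["phosphorus"]],
                   fc_component = fc[["component"]],
                   area_rice = areas[1], area_wheat = areas[2],
                   area_maize = areas[3],
                   area_total = sum(areas),
                   area_other = areas[4],
                   cropland_area = sum(areas), stringsAsFactors = FALSE)
  if (is.null(prov_rates)) {
    prov_rates <- data.frame(province = "P1", year = 2004L,
                             crop = crop_categories(),
                             kind = rep(fertilizer_kinds(), each = 4),
                             rate = 1, flag = "derived",
                             stringsAsFactors = FALSE)
  }
  list(prov = prov_rates, cs = cs)
}

test_that("allocation ratios follow the provincial-rate x area weighting", {
  # county growing only rice: rice takes everything
  sc <- one_county(c(5e5, 0, 0, 0))
  rat <- allocation_ratios(sc$prov, sc$cs)
  p <- rat[rat$kind == "phosphorus", ]
  expect_equal(p$ratio[p$crop == "rice"], 1)
  expect_equal(p$ratio[p$crop != "rice"], rep(0, 3))

  # equal rates and equal areas: a quarter each
  sc <- one_county(rep(2e5, 4))
  rat <- allocation_ratios(sc$prov, sc$cs)
  expect_equal(rat$ratio, rep(0.25, 8))

  # hand-evaluated weighting: rates (6.5, 8.7, 6.4, 3.0) g/m2 with areas
  # (2, 1, 1, 4) x 1e6 m2 -> terms (13, 8.7, 6.4, 12) x 1e6, denominator
  # 40.1e6
  pr <- data.frame(province = "P1", year = 2004L,
                   crop = rep(crop_categories(), 2),
                   kind = rep(fertilizer_kinds(), each = 4),
                   rate = rep(c(6.5, 8.7, 6.4, 3.0), 2),
                   flag = "derived", stringsAsFactors = FALSE)
  sc <- one_county(c(2e6, 1e6, 1e6, 4e6), prov_rates = pr)
  rat <- allocation_ratios(pr, sc$cs)
  p <- rat$ratio[rat$kind == "phosphorus"]
  expect_equal(p, c(13, 8.7, 6.4, 12) / 40.1, tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("ratio edge policies: missing areas, zero denominator, no other rate", {
  sc <- one_county(c(NA, 1, 1, 1))
  rat <- allocation_ratios(sc$prov, sc$cs)
  expect_true(all(is.na(rat$ratio)))
  expect_true(all(rat$flag == "missing"))

  sc <- one_county(c(0, 0, 0, 0))
  rat <- allocation_ratios(sc$prov, sc$cs)
  expect_true(all(is.na(rat$ratio)))
  expect_true(all(rat$flag == "undefined"))

  # province with an undefined other-crops rate: allocate over named crops
  pr <- data.frame(province = "P1", year = 2004L,
                   crop = rep(crop_categories(), 2),
                   kind = rep(fertilizer_kinds(), each = 4),
                   rate = rep(c(2, 2, 2, NA), 2),
                   flag = rep(c(rep("observed", 3), "undefined"), 2),
                   stringsAsFactors = FALSE)
  sc <- one_county(c(1e5, 1e5, 1e5, 3e5), prov_rates = pr)
  rat <- allocation_ratios(pr, sc$cs)
  named <- rat[rat$crop != "other", ]
  expect_equal(named$ratio, rep(1 / 3, 6), tolerance = 1e-12)
  expect_equal(unique(rat$flag[rat$crop == "other"]), "no_other_rate")
  expect_true(all(is.na(rat$ratio[rat$crop == "other"])))

  expect_error(allocation_ratios(sc$prov,
                                 transform(sc$cs, province = "PX")),
               "unknown province")
})

test_that("allocated consumptions multiply out and conserve the total", {
  ratios <- data.frame(county = "C1", province = "P1", year = 2004L,
                       kind = "phosphorus", crop = crop_categories(),
                       ratio = c(0.5, 0.3, 0.1, 0.1), flag = "derived",
                       stringsAsFactors = FALSE)
  cs <- one_county(c(1, 1, 1, 1))$cs
  cons <- allocate_consumption(ratios, cs)
  expect_equal(cons$consumption, c(500, 300, 100, 100))

  cs$fc_phosphorus <- 0
  expect_equal(allocate_consumption(ratios, cs)$consumption, rep(0, 4))

  cs$fc_phosphorus <- NA_real_
  cons <- allocate_consumption(ratios, cs)
  expect_true(all(is.na(cons$consumption)))
  expect_true(all(cons$flag == "missing"))
})

test_that("county rates divide consumption by area with NaN-free policies", {
  cons <- data.frame(county = "C1", province = "P1", year = 2004L,
                     kind = rep(fertilizer_kinds(), each = 4),
                     crop = rep(crop_categories(), 2),
                     consumption = c(650, 0, 0, 0, 0, 0, 0, 0),
                     flag = "derived", stringsAsFactors = FALSE)
  cs <- one_county(c(100, 0, 50, 10))$cs
  rates <- county_rates(cons, cs)
  expect_equal(rates$rate_phosphorus[rates$crop == "rice"], 6.5)
  # zero area, zero consumption: undefined, not NaN
  expect_true(is.na(rates$rate_phosphorus[rates$crop == "wheat"]))
  expect_equal(rates$flag_phosphorus[rates$crop == "wheat"], "undefined")
  expect_false(any(is.nan(unlist(rates$rate_phosphorus))))

  cons$consumption[2] <- 5  # wheat has zero area
  expect_error(county_rates(cons, cs), "zero growing area")
})

test_that("allocation conserves mass and scales with the county total", {
  w <- tiny_world(seed = 16, flavor = "heterogeneous", missing_rate = 0.05)
  res <- run_pipeline_world(w)
  cons <- res$consumption
  cs <- res$county_filled
  k <- paste(cons$county, cons$year, cons$kind)
  s <- tapply(cons$consumption, k, sum)
  fc <- ifelse(grepl("phosphorus$", names(s)),
               cs$fc_phosphorus[match(sub(" [a-z]+$", "", names(s)),
                                      paste(cs$county, cs$year))],
               cs$fc_component[match(sub(" [a-z]+$", "", names(s)),
                                     paste(cs$county, cs$year))])
  expect_lt(max_rel_err(as.numeric(s), fc), 1e-9)

  # scale equivariance: doubling county totals doubles the rates
  w2 <- w
  w2$county_stats$fc_phosphorus <- 2 * w2$county_stats$fc_phosphorus
  w2$county_stats$fc_component <- 2 * w2$county_stats$fc_component
  res2 <- run_pipeline_world(w2)
  expect_equal(res2$rates$rate_phosphorus, 2 * res$rates$rate_phosphorus,
               tolerance = 1e-12)

  # area-unit invariance: a common area rescaling leaves ratios unchanged
  w3 <- w
  acols <- c("area_rice", "area_wheat", "area_maize", "area_total",
             "area_other")
  w3$county_stats[acols] <- w3$county_stats[acols] * 1e-4
  rat <- allocation_ratios(provincial_stage(w$provincial_rates,
                                            w$provincial_totals)$rates,
                           gap_fill_county(w$county_stats))
  rat3 <- allocation_ratios(provincial_stage(w$provincial_rates,
                                             w$provincial_totals)$rates,
                            gap_fill_county(w3$county_stats))
  expect_equal(rat3$ratio, rat$ratio, tolerance = 1e-9)
})

test_that("county rates equal generator truth in the uniform regime", {
  w <- tiny_world(seed = 17)
  res <- run_pipeline_world(w)
  m <- merge(res$rates, w$truth, by = c("county", "province", "year", "crop"))
  expect_gt(nrow(m), 0)
  expect_lt(max_rel_err(m$rate_phosphorus.x, m$rate_phosphorus.y), 1e-9)
  expect_lt(max_rel_err(m$rate_component.x, m$rate_component.y), 1e-9)
  expect_lt(max_rel_err(m$p2o5_rate.x, m$p2o5_rate.y), 1e-9)
})

test_that("pipeline tolerates the injected pathologies by policy", {
  # overshoot: clamped other rate, county other category gets zero share
  w <- perturb_world(tiny_world(seed = 18), "overshoot_crops")
  st <- provincial_stage(w$provincial_rates, w$provincial_totals)
  expect_true(any(st$rates$flag == "clamped"))
  res <- run_pipeline_world(w)
  expect_true(all(res$rates$p2o5_rate >= 0, na.rm = TRUE))

  # zero-area county with positive consumption: ratios undefined, flagged
  wz <- perturb_world(tiny_world(seed = 18), "zero_area_county")
  res <- run_pipeline_world(wz)
  z <- wz$county_stats[wz$county_stats$area_total == 0 &
                         wz$county_stats$fc_phosphorus > 0, ]
  hit <- res$ratios[res$ratios$county == z$county[1] &
                      res$ratios$year == z$year[1], ]
  expect_true(all(hit$flag == "undefined"))
})
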