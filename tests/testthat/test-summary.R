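mini_rates <- function(rates_by_county, areas_by_county, years = 2004:2006,
                       crop = "rice") {
  counties <- names(rates_by_county)
  df <- expand.grid(county = counties, year = years,
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  df$province <- "P1"
  df$crop <- crop
  df$rate_phosphorus <- unlist(rates_by_county)[df$county]
  df$flag_phosphorus <- "derived"
  df$rate_component <- 0
  df$flag_component <- "derived"
  df$p2o5_rate <- df$rate_phosphorus
  df$flag_p2o5 <- "derived"
  cs <- data.frame(county = df$county, province = "P1", year = df$year,
                   fc_phosphorus = 0, fc_component = 0,
                   area_rice = unlist(areas_by_county)[df$county],
                   area_wheat = 0, area_maize = 0,
                   area_total = unlist(areas_by_county)[df$county],
                   area_other = 0,
                   cropland_area = unlist(areas_by_county)[df$county],
                   stringsAsFactors = FALSE)
  cs <- unique(cs)
  list(rates = df, cs = cs)
}

test_that("the national series is the area-weighted county mean", {
  sc <- mini_rates(list(C1 = 5), list(C1 = 1e6))
  ns <- national_series(sc$rates, sc$cs, "rice")
  expect_equal(ns$mean_rate, rep(5, 3))

  sc <- mini_rates(list(C1 = 4, C2 = 8), list(C1 = 1, C2 = 3))
  ns <- national_series(sc$rates, sc$cs, "rice")
  expect_equal(ns$mean_rate, rep(7, 3))
  expect_equal(ns$n_counties, rep(2L, 3))

  # brute-force double-loop oracle on a synthetic world
  w <- tiny_world(seed = 23, flavor = "heterogeneous")
  res <- run_pipeline_world(w)
  ns <- national_series(res$rates, res$county_filled, "wheat")
  for (yi in seq_along(ns$year)) {
    num <- 0; den <- 0
    for (cty in unique(res$rates$county)) {
      r <- res$rates[res$rates$county == cty & res$rates$year == ns$year[yi] &
                       res$rates$crop == "wheat", ]
      a <- res$county_filled$area_wheat[res$county_filled$county == cty &
                                  res$county_filled$year == ns$year[yi]]
      if (nrow(r) == 1 && !is.na(r$p2o5_rate) && !is.na(a) && a > 0) {
        num <- num + r$p2o5_rate * a
        den <- den + a
      }
    }
    expect_equal(ns$mean_rate[yi], num / den, tolerance = 1e-9)
  }

  # sub-crop pooling by joint area weighting
  both <- national_series(res$rates, res$county_filled, c("rice", "wheat"))
  r1 <- national_series(res$rates, res$county_filled, "rice")
  r2 <- national_series(res$rates, res$county_filled, "wheat")
  pooled <- (r1$mean_rate * r1$total_area + r2$mean_rate * r2$total_area) /
    (r1$total_area + r2$total_area)
  expect_equal(both$mean_rate, pooled, tolerance = 1e-12)
})

test_that("relative trend handles constant, exact and noisy series", {
  const <- structure(data.frame(year = 2004:2016, mean_rate = 5),
                     class = c("national_series", "data.frame"),
                     crop = "rice")
  tr <- relative_trend(const)
  expect_equal(tr$relative_trend, 0)
  expect_equal(tr$p_value, 1)
  expect_true(tr$degenerate)

  line <- structure(data.frame(year = 2004:2016,
                               mean_rate = 2 + 0.1 * (0:12)),
                    class = c("national_series", "data.frame"),
                    crop = "wheat")
  tr <- relative_trend(line)
  expect_equal(tr$slope, 0.1, tolerance = 1e-12)
  expect_equal(tr$p_value, 0)
  expect_true(tr$degenerate)
  expect_equal(tr$relative_trend, 100 * 0.1 / mean(line$mean_rate),
               tolerance = 1e-12)

  set.seed(51)
  noisy <- structure(data.frame(year = 2004:2016,
                                mean_rate = 6 + 0.05 * (0:12) + rnorm(13, 0, 0.3)),
                     class = c("national_series", "data.frame"),
                     crop = "maize")
  tr <- relative_trend(noisy)
  want <- ols_oracle(noisy$year, noisy$mean_rate)
  expect_equal(tr$slope, want$slope, tolerance = 1e-8)
  expect_equal(tr$p_value, want$p, tolerance = 1e-8)

  expect_error(relative_trend(const[1:2, ]), "at least 3 years")
})

test_that("trend is invariant to a constant shift of the series", {
  set.seed(52)
  s <- structure(data.frame(year = 2004:2016,
                            mean_rate = 4 + 0.1 * (0:12) + rnorm(13, 0, 0.2)),
                 class = c("national_series", "data.frame"), crop = "rice")
  t0 <- relative_trend(s)
  s2 <- s
  s2$mean_rate <- s$mean_rate + 10
  t1 <- relative_trend(s2)
  expect_equal(t1$slope, t0$slope, tolerance = 1e-10)
  expect_equal(t1$p_value, t0$p_value, tolerance = 1e-10)
  expect_equal(t1$relative_trend,
               100 * t0$slope / (t0$period_mean + 10), tolerance = 1e-10)
})

test_that("Tukey HSD letters behave at the extremes and under relabeling", {
  mk <- function(v, crop) structure(data.frame(year = 2004:2016, mean_rate = v),
                                    class = c("national_series", "data.frame"),
                                    crop = crop)
  set.seed(53)
  base <- rnorm(13, 5, 0.3)
  # identical groups: everyone shares one letter
  th <- tukey_hsd(list(a = mk(base, "a"), b = mk(base, "b"),
                       c = mk(base, "c")))
  expect_true(all(th$letters == th$letters[1]))
  expect_true(all(nchar(th$letters) == 1))

  # groups a hundred pooled SDs apart: all letters distinct
  th2 <- tukey_hsd(list(lo = mk(base, "lo"), hi = mk(base + 100, "hi"),
                        vhi = mk(base + 200, "vhi")))
  expect_equal(length(unique(th2$letters)), 3)

  # relabeling permutes the letters but not the partition
  g1 <- mk(rnorm(13, 5, 0.3), "x")
  g2 <- mk(rnorm(13, 5.1, 0.3), "y")
  g3 <- mk(rnorm(13, 9, 0.3), "z")
  ta <- tukey_hsd(list(x = g1, y = g2, z = g3))
  tb <- tukey_hsd(list(z = g3, x = g1, y = g2))
  same_letter <- function(l, a, b) {
    length(intersect(strsplit(l[[a]], "")[[1]],
                     strsplit(l[[b]], "")[[1]])) > 0
  }
  for (p in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    expect_equal(same_letter(ta$letters, p[1], p[2]),
                 same_letter(tb$letters, p[1], p[2]))
  }

  expect_error(tukey_hsd(list(a = mk(base, "a"),
                              b = mk(base, "b")[1:10, ])),
               "unequal year coverage")
})

test_that("total consumption series is linear and partition-additive", {
  w <- tiny_world(seed = 24, flavor = "heterogeneous")
  cs <- w$county_stats
  ts <- total_consumption_series(cs, w$weights)

  # generator closed form: sum over county truth
  tr <- w$truth
  content <- weighted_p2o5_content(tr$year, w$weights)
  want <- tapply((tr$rate_phosphorus + tr$rate_component * content) * tr$area,
                 tr$year, sum)
  expect_lt(max_rel_err(ts$total_p2o5, as.numeric(want)), 1e-9)

  # single county, no component fertilizer
  one <- cs[cs$county == cs$county[1], ]
  one$fc_component <- 0
  t1 <- total_consumption_series(one, w$weights)
  expect_equal(t1$total_p2o5, one$fc_phosphorus[order(one$year)])

  # doubling inputs doubles the series
  cs2 <- cs
  cs2$fc_phosphorus <- 2 * cs2$fc_phosphorus
  cs2$fc_component <- 2 * cs2$fc_component
  expect_equal(total_consumption_series(cs2, w$weights)$total_p2o5,
               2 * ts$total_p2o5, tolerance = 1e-12)

  # partition additivity over provinces
  parts <- lapply(split(cs, cs$province), total_consumption_series,
                  weights = w$weights)
  summed <- Reduce(`+`, lapply(parts, `[[`, "total_p2o5"))
  expect_equal(summed, ts$total_p2o5, tolerance = 1e-12)
})

test_that("per-cropland maps divide consumption by cropland and rasterize", {
  w <- tiny_world(seed = 25)
  yr <- w$config$years[1]
  cs <- w$county_stats
  map <- per_cropland_rate_map(cs, w$weights, w$county_raster,
                               w$cropland_mask, yr)
  # composition identity with the shared rasterizer
  sub <- cs[cs$year == yr, ]
  val <- (sub$fc_phosphorus +
            sub$fc_component * weighted_p2o5_content(yr, w$weights)) /
    sub$cropland_area
  want <- rasterize_county_values(setNames(val, sub$county),
                                  w$county_raster, w$cropland_mask)
  expect_identical(map$values, want$values)

  # hand value: 2000 g over 100 m2 of cropland -> 20 g/m2
  cs2 <- sub[1, ]
  cs2$fc_phosphorus <- 2000
  cs2$fc_component <- 0
  cs2$cropland_area <- 100
  m2 <- per_cropland_rate_map(cs2, w$weights, w$county_raster,
                              w$cropland_mask, yr)
  expect_equal(unique(m2$values[!is.na(m2$values)]), 20)

  cs2$cropland_area <- 0
  expect_error(per_cropland_rate_map(cs2, w$weights, w$county_raster,
                                     w$cropland_mask, yr), "zero cropland")
})
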