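#' Area-weighted national annual mean rate for a crop
#'
#' For each year, the national mean is the county rates weighted by the
#' county growing areas: `sum_j FR_j * A_j / sum_j A_j`. Sub-crop variants
#' (e.g. single/double-season rice carried as separate categories) can be
#' pooled by passing several categories in `crop`; they are combined by
#' area weighting in the same sum before (i.e. jointly with) the national
#' aggregation.
#'
#' Only counties with a defined P2O5 rate contribute; a year in which no
#' county contributes any growing area is an error.
#'
#' @param rates county rate table with `p2o5_rate`.
#' @param county_stats county statistics table (areas).
#' @param crop crop category, or several to pool by area weighting.
#' @return data frame `year, mean_rate, total_area, n_counties` with
#'   attribute `"crop"`; class `national_series`.
#' @export
national_series <- function(rates, county_stats, crop) {
  stopifnot(all(crop %in% crop_categories()))
  area_col <- c(rice = "area_rice", wheat = "area_wheat",
                maize = "area_maize", other = "area_other")
  sub <- rates[rates$crop %in% crop & !is.na(rates$p2o5_rate), ]
  if (!nrow(sub)) stop("no defined rates for crop ", paste(crop, collapse = "+"),
                       call. = FALSE)
  i <- match(paste(sub$county, sub$year),
             paste(county_stats$county, county_stats$year))
  A <- vapply(seq_len(nrow(sub)), function(r) {
    county_stats[[area_col[[sub$crop[r]]]]][i[r]]
  }, numeric(1))
  ok <- !is.na(A) & A > 0
  sub <- sub[ok, ]; A <- A[ok]
  years <- sort(unique(rates$year))
  k <- factor(sub$year, levels = years)
  num <- tapply(sub$p2o5_rate * A, k, sum)
  den <- tapply(A, k, sum)
  n <- tapply(A, k, length)
  if (any(is.na(den) | den == 0)) {
    stop("year(s) with zero contributing growing area: ",
         paste(years[is.na(den) | den == 0], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(year = years, mean_rate = as.numeric(num / den),
                    total_area = as.numeric(den),
                    n_counties = as.integer(n))
  attr(out, "crop") <- paste(crop, collapse = "+")
  class(out) <- c("national_series", class(out))
  rownames(out) <- NULL
  out
}

#' Relative time trend of a national series
#'
#' Ordinary least squares of the annual mean rate on calendar year. The
#' slope's p-value is the two-sided t-test on the slope coefficient; the
#' relative trend is `100 * slope / period mean` of the series, in % per
#' year. A perfect fit (zero residual) cannot support a t-test and is
#' flagged degenerate: p = 1 for a constant series (slope 0), p = 0 for an
#' exact non-constant line.
#'
#' @param series a [national_series()] (>= 3 years).
#' @return one-row data frame `crop, slope, p_value, period_mean,
#'   relative_trend, degenerate`.
#' @export
relative_trend <- function(series) {
  if (nrow(series) < 3L) stop("need at least 3 years for a trend",
                              call. = FALSE)
  y <- series$mean_rate
  x <- series$year
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  rss <- sum(fit$residuals^2)
  scale <- max(sum((y - mean(y))^2), .Machine$double.xmin)
  degenerate <- rss <= 1e-20 * max(scale, mean(y)^2)
  if (degenerate) {
    p <- if (abs(slope) <= 1e-12 * max(abs(y), 1)) 1 else 0
  } else {
    se <- sqrt(rss / (length(y) - 2) / sum((x - mean(x))^2))
    p <- 2 * pt(abs(slope / se), df = length(y) - 2, lower.tail = FALSE)
  }
  pm <- mean(y)
  data.frame(crop = attr(series, "crop") %||% NA_character_,
             slope = slope, p_value = p, period_mean = pm,
             relative_trend = 100 * slope / pm,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tukey HSD contrasts between crops
#'
#' One-way layout with crops as groups and the annual national means as
#' replicates (so the sample unit is the year and every group must cover
#' the same years). Pairwise honestly-significant-difference p-values come
#' from the studentized-range distribution; groups are then labeled with a
#' compact letter display at the chosen alpha — groups sharing a letter are
#' not significantly different.
#'
#' @param series_by_crop named list of [national_series()] objects
#'   (>= 2 crops).
#' @param alpha significance level for the letter display.
#' @return list with `p` (data frame `pair, diff, p_adj`), `letters`
#'   (named character vector), `means` (group means).
#' @export
tukey_hsd <- function(series_by_crop, alpha = 0.05) {
  stopifnot(length(series_by_crop) >= 2L)
  if (is.null(names(series_by_crop)) || any(names(series_by_crop) == "")) {
    names(series_by_crop) <- vapply(series_by_crop, function(s)
      attr(s, "crop") %||% "", "")
  }
  yrs <- lapply(series_by_crop, function(s) sort(s$year))
  for (i in seq_along(yrs)[-1]) {
    if (!identical(yrs[[i]], yrs[[1]])) {
      stop("unequal year coverage across crops", call. = FALSE)
    }
  }
  df <- do.call(rbind, lapply(names(series_by_crop), function(g) {
    data.frame(group = g, value = series_by_crop[[g]]$mean_rate,
               stringsAsFactors = FALSE)
  }))
  df$group <- factor(df$group, levels = names(series_by_crop))
  fit <- aov(value ~ group, data = df)
  th <- TukeyHSD(fit, "group", conf.level = 1 - alpha)$group
  p <- data.frame(pair = rownames(th), diff = th[, "diff"],
                  p_adj = th[, "p adj"], stringsAsFactors = FALSE)
  rownames(p) <- NULL
  means <- tapply(df$value, df$group, mean)
  letters_out <- .compact_letters(levels(df$group), p, means, alpha)
  list(p = p, letters = letters_out, means = means)
}

# insert-and-absorb compact letter display
.compact_letters <- function(groups, p, means, alpha) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (r in seq_len(nrow(p))) {
    gg <- strsplit(p$pair[r], "-", fixed = TRUE)[[1]]
    if (p$p_adj[r] < alpha) {
      sig[gg[1], gg[2]] <- TRUE
      sig[gg[2], gg[1]] <- TRUE
    }
  }
  cols <- list(seq_len(k))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  canon <- function(cs) unique(lapply(cs, sort))
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      nxt <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          nxt <- c(nxt, list(setdiff(col, i)), list(setdiff(col, j)))
        } else nxt <- c(nxt, list(col))
      }
      nxt <- canon(nxt)
      keep <- rep(TRUE, length(nxt))
      for (a in seq_along(nxt)) {
        for (b in seq_along(nxt)) {
          if (a != b && keep[b] && length(nxt[[a]]) < length(nxt[[b]]) &&
              all(nxt[[a]] %in% nxt[[b]])) keep[a] <- FALSE
        }
      }
      cols <- nxt[keep]
    }
  }
  # letter columns ordered by their best (largest-mean) member
  rank_of <- rank(-means, ties.method = "first")
  ord <- order(vapply(cols, function(col) min(rank_of[col]), numeric(1)))
  cols <- cols[ord]
  out <- setNames(rep("", k), groups)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) out[g] <- paste0(out[g], letters[ci])
  }
  out
}

#' National total P2O5 consumption per year from county statistics
#'
#' For each year, sums `FC_phosphorus + FC_component * weighted content`
#' over all counties with both totals reported (missing county-years are
#' excluded and counted). Linear and monotone in every input.
#'
#' @param county_stats county statistics table (ideally gap-filled).
#' @param weights a [composition_weights()] table.
#' @return data frame `year, total_p2o5, n_counties` (g P2O5).
#' @export
total_consumption_series <- function(county_stats, weights) {
  content <- weighted_p2o5_content(county_stats$year, weights)
  v <- county_stats$fc_phosphorus + county_stats$fc_component * content
  ok <- !is.na(v)
  years <- sort(unique(county_stats$year))
  k <- factor(county_stats$year[ok], levels = years)
  data.frame(year = years,
             total_p2o5 = as.numeric(tapply(v[ok], k, sum, default = 0)),
             n_counties = as.integer(tapply(v[ok], k, length, default = 0L)))
}

#' Total agricultural P2O5 rate per cropland, rasterized
#'
#' County value = total P2O5 consumption (both kinds) divided by physical
#' cropland area — the per-cropland rate used for dataset intercomparison,
#' distinct from the per-growing-area rates (cropland can host several
#' crop seasons). Rasterized over the cropland mask exactly like the
#' crop-specific maps.
#'
#' @param county_stats county statistics table.
#' @param weights a [composition_weights()] table.
#' @param county_raster county-ID raster.
#' @param cropland_mask presence raster for cropland.
#' @param year the year to map.
#' @return a `rate_map`.
#' @export
per_cropland_rate_map <- function(county_stats, weights, county_raster,
                                  cropland_mask, year) {
  cs <- county_stats[county_stats$year == year, ]
  content <- weighted_p2o5_content(year, weights)
  total <- cs$fc_phosphorus + cs$fc_component * content
  bad <- !is.na(total) & total > 0 & !is.na(cs$cropland_area) &
    cs$cropland_area == 0
  if (any(bad)) {
    stop("positive consumption over zero cropland for county(ies): ",
         paste(cs$county[bad], collapse = ", "), call. = FALSE)
  }
  val <- ifelse(!is.na(cs$cropland_area) & cs$cropland_area > 0,
                total / cs$cropland_area, NA_real_)
  out <- rasterize_county_values(setNames(val, cs$county), county_raster,
                                 cropland_mask)
  attr(out, "crop") <- "cropland"
  attr(out, "year") <- as.integer(year)
  class(out) <- c("rate_map", class(out))
  out
}

#' National annual mean rate from a directory of rate maps
#'
#' The map-based aggregation path: reads every `CNP_<crop>_<year>.tif` for
#' the crop and averages the finite pixels per year. Pixels weight equally,
#' so this equals area weighting only insofar as pixel counts are
#' proportional to growing areas; the table-based [national_series()] is
#' the exact-weighting path.
#'
#' @param dir directory of rate maps.
#' @param crop crop category.
#' @return data frame `year, mean_rate, n_pixels`; class `national_series`.
#' @export
map_national_series <- function(dir, crop) {
  files <- list.files(dir, pattern = sprintf("^CNP_%s_[0-9]{4}\\.tif$", crop),
                      full.names = TRUE)
  if (!length(files)) stop("no rate maps for crop ", crop, " in ", dir,
                           call. = FALSE)
  rows <- lapply(sort(files), function(f) {
    m <- read_ratemap(f)
    v <- m$values[is.finite(m$values)]
    data.frame(year = attr(m, "year"), mean_rate = mean(v),
               n_pixels = length(v))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$year), ]
  attr(out, "crop") <- crop
  class(out) <- c("national_series", class(out))
  rownames(out) <- NULL
  out
}
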