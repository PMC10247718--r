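#' Gap-filling policy for county time series
#'
#' County yearbook series have sporadic missing years. Interior missing
#' runs of at most `max_run` consecutive years are filled with a natural
#' cubic spline through all observed points; longer runs and gaps touching
#' the series boundary are left missing. The default `max_run = 2` encodes
#' filling only when data are unavailable for fewer than 3 consecutive
#' years.
#'
#' @param max_run longest missing run that may be filled (>= 0).
#' @param method interpolation method; only `"cubic_spline"` (natural
#'   boundary conditions) is implemented.
#' @param extrapolate fill boundary gaps by spline extrapolation (default
#'   FALSE: boundary gaps stay missing).
#' @param floor_at_zero clamp filled values below zero to zero (rates,
#'   areas and consumptions are non-negative quantities).
#' @return a `gap_fill_policy` list.
#' @export
gap_fill_policy <- function(max_run = 2L, method = "cubic_spline",
                            extrapolate = FALSE, floor_at_zero = TRUE) {
  method <- match.arg(method, "cubic_spline")
  stopifnot(length(max_run) == 1L, max_run >= 0)
  structure(list(max_run = as.integer(max_run), method = method,
                 extrapolate = isTRUE(extrapolate),
                 floor_at_zero = isTRUE(floor_at_zero)),
            class = "gap_fill_policy")
}

#' Fill missing values in an annual series by natural cubic spline
#'
#' @param years consecutive integer years indexing the series.
#' @param values numeric values with NA marking missing years.
#' @param policy a [gap_fill_policy()].
#' @return list with `values` (filled series) and `status` (per year:
#'   `"observed"`, `"gap_filled"` or `"missing"`).
#' @examples
#' gap_fill_series(2004:2008, c(10, 20, NA, 40, 50))$values[3]  # 30
#' @export
gap_fill_series <- function(years, values, policy = gap_fill_policy()) {
  stopifnot(inherits(policy, "gap_fill_policy"),
            length(years) == length(values))
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("series must be indexed by consecutive years", call. = FALSE)
  }
  obs <- !is.na(values)
  status <- ifelse(obs, "observed", "missing")
  if (all(obs) || !any(obs)) {
    return(list(values = values, status = status))
  }

  fill_idx <- .fillable_runs(obs, policy$max_run, policy$extrapolate)
  if (!length(fill_idx)) {
    return(list(values = values, status = status))
  }
  if (sum(obs) < 4L) {
    stop("fewer than 4 observed points; cannot construct the cubic spline",
         call. = FALSE)
  }
  fit <- spline(x = years[obs], y = values[obs], method = "natural",
                xout = years[fill_idx])
  filled <- fit$y
  if (policy$floor_at_zero) filled <- pmax(0, filled)
  values[fill_idx] <- filled
  status[fill_idx] <- "gap_filled"
  list(values = values, status = status)
}

# indices of missing entries belonging to runs that the policy allows to fill
.fillable_runs <- function(obs, max_run, extrapolate) {
  r <- rle(obs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) next
    boundary <- i == 1L || i == length(r$lengths)
    if (boundary && !extrapolate) next
    if (r$lengths[i] > max_run) next
    out <- c(out, starts[i]:ends[i])
  }
  out
}

#' Gap-fill a county statistics table
#'
#' Applies [gap_fill_series()] per county to the pipeline inputs — the two
#' total-consumption series and the four sown-area series — then recomputes
#' the residual other-crops area from the filled components. Ratios and
#' rates are never interpolated directly; they are recomputed downstream
#' from the filled inputs so that mass conservation holds after filling.
#'
#' Counties with fewer than 4 observed points in a series keep their gaps
#' (logged), rather than aborting the whole table.
#'
#' @param county_stats validated county statistics table.
#' @param policy a [gap_fill_policy()].
#' @return the table with filled values and, per filled column, a
#'   `<col>_src` provenance column; attribute `"gapfill_log"` counts
#'   observed / filled / missing cells per column.
#' @export
gap_fill_county <- function(county_stats, policy = gap_fill_policy()) {
  validate_county_stats(county_stats)
  df <- county_stats[order(county_stats$county, county_stats$year), ,
                     drop = FALSE]
  cols <- c("fc_phosphorus", "fc_component", "area_rice", "area_wheat",
            "area_maize", "area_total")
  for (cl in cols) df[[paste0(cl, "_src")]] <- ifelse(is.na(df[[cl]]),
                                                      "missing", "observed")
  too_short <- 0L
  for (cty in unique(df$county)) {
    sel <- which(df$county == cty)
    yrs <- df$year[sel]
    for (cl in cols) {
      v <- df[[cl]][sel]
      if (!anyNA(v) || all(is.na(v))) next
      res <- tryCatch(gap_fill_series(yrs, v, policy), error = function(e) e)
      if (inherits(res, "error")) { too_short <- too_short + 1L; next }
      df[[cl]][sel] <- res$values
      df[[paste0(cl, "_src")]][sel] <- ifelse(res$status == "gap_filled",
                                              "gap_filled",
                                              df[[paste0(cl, "_src")]][sel])
    }
  }
  # residual other-crops area from the (possibly filled) components
  df$area_other <- other_area(df$area_total, df$area_rice, df$area_wheat,
                              df$area_maize)
  log <- do.call(rbind, lapply(cols, function(cl) {
    src <- df[[paste0(cl, "_src")]]
    data.frame(column = cl, observed = sum(src == "observed"),
               gap_filled = sum(src == "gap_filled"),
               missing = sum(src == "missing"))
  }))
  attr(df, "gapfill_log") <- log
  attr(df, "series_too_short") <- too_short
  rownames(df) <- NULL
  df
}
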