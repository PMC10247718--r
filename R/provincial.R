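#' Provincial crop-specific fertilizer consumption
#'
#' Multiplies each provincial crop-specific rate (named crops) by the
#' matching sown area to obtain crop-specific consumption per
#' province-year-kind, in grams.
#'
#' @param rates provincial rate table (named crops; see
#'   [validate_provincial_rates()]).
#' @param totals provincial totals table.
#' @return data frame `province, year, crop, kind, consumption` (g).
#' @export
crop_consumption <- function(rates, totals) {
  validate_provincial_rates(rates)
  validate_provincial_totals(totals)
  i <- match(paste(rates$province, rates$year),
             paste(totals$province, totals$year))
  if (anyNA(i)) {
    stop("no totals row for province-year(s): ",
         paste(unique(paste(rates$province, rates$year)[is.na(i)]),
               collapse = ", "), call. = FALSE)
  }
  area_col <- paste0("area_", rates$crop)
  area <- vapply(seq_len(nrow(rates)),
                 function(r) totals[[area_col[r]]][i[r]], numeric(1))
  if (anyNA(area)) {
    stop("missing sown area for ", sum(is.na(area)), " rate record(s)",
         call. = FALSE)
  }
  data.frame(province = rates$province, year = rates$year, crop = rates$crop,
             kind = rates$kind, consumption = rates$rate * area,
             stringsAsFactors = FALSE)
}

#' Residual other-crops rate per province-year
#'
#' Subtracts the named crops' consumption from the provincial total to get
#' the other-crops consumption, then divides by the other-crops sown area
#' (total minus named). A negative residual is clamped to zero and flagged
#' `"clamped"` — negative mass is never propagated. A positive residual
#' over zero other-crops area is flagged `"undefined"` and no rate is
#' emitted (downstream allocation then treats the category as zero-weight).
#'
#' @param consumption named-crop consumption from [crop_consumption()].
#' @param totals provincial totals table.
#' @param rates the provincial rate table the consumption came from.
#' @return provincial rate table extended with the `"other"` category and a
#'   `flag` column (`"observed"` for named crops, `"derived"`, `"clamped"`
#'   or `"undefined"` for the residual).
#' @export
other_crops_rate <- function(consumption, totals, rates) {
  validate_provincial_totals(totals)
  validate_provincial_rates(rates)
  keys <- unique(consumption[c("province", "year", "kind")])
  i <- match(paste(keys$province, keys$year),
             paste(totals$province, totals$year))
  if (anyNA(i)) {
    stop("totals row absent for province-year-kind(s): ",
         paste(paste(keys$province, keys$year, keys$kind)[is.na(i)],
               collapse = ", "), call. = FALSE)
  }
  total <- ifelse(keys$kind == "phosphorus",
                  totals$consumption_phosphorus[i],
                  totals$consumption_component[i])
  area_o <- other_area(totals$area_total[i], totals$area_rice[i],
                       totals$area_wheat[i], totals$area_maize[i])
  # fixed ascending crop enumeration order for the deterministic sum
  named_sum <- vapply(seq_len(nrow(keys)), function(r) {
    s <- 0
    for (cr in named_crops()) {
      v <- consumption$consumption[consumption$province == keys$province[r] &
                                   consumption$year == keys$year[r] &
                                   consumption$kind == keys$kind[r] &
                                   consumption$crop == cr]
      if (length(v)) s <- s + v
    }
    s
  }, numeric(1))

  residual <- total - named_sum
  clamped <- residual < 0
  residual[clamped] <- 0
  undefined <- area_o == 0 & residual > 0
  zero_zero <- area_o == 0 & residual == 0
  rate <- ifelse(area_o > 0, residual / area_o, NA_real_)
  flag <- ifelse(undefined | zero_zero, "undefined",
                 ifelse(clamped, "clamped", "derived"))
  rate[clamped & area_o > 0] <- 0

  other <- data.frame(province = keys$province, year = keys$year,
                      crop = "other", kind = keys$kind, rate = rate,
                      flag = flag, stringsAsFactors = FALSE)
  named <- rates
  named$flag <- "observed"
  out <- rbind(named[c("province", "year", "crop", "kind", "rate", "flag")],
               other)
  out <- out[order(out$province, out$year, out$kind,
                   match(out$crop, crop_categories())), , drop = FALSE]
  rownames(out) <- NULL
  validate_provincial_rates(out, allow_other = TRUE)
  out
}

#' Full provincial stage
#'
#' Runs [crop_consumption()] and [other_crops_rate()] and also returns the
#' four-crop provincial consumption table (the residual category's
#' consumption is the clamped residual).
#'
#' @inheritParams crop_consumption
#' @return list with `rates` (four-crop provincial rate table with flags)
#'   and `consumption` (four-crop consumption table).
#' @export
provincial_stage <- function(rates, totals) {
  cons <- crop_consumption(rates, totals)
  full <- other_crops_rate(cons, totals, rates)
  oth <- full[full$crop == "other", ]
  i <- match(paste(oth$province, oth$year),
             paste(totals$province, totals$year))
  area_o <- other_area(totals$area_total[i], totals$area_rice[i],
                       totals$area_wheat[i], totals$area_maize[i])
  cons_other <- data.frame(province = oth$province, year = oth$year,
                           crop = "other", kind = oth$kind,
                           consumption = ifelse(is.na(oth$rate), NA_real_,
                                                oth$rate * area_o),
                           stringsAsFactors = FALSE)
  list(rates = full, consumption = rbind(cons, cons_other))
}
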