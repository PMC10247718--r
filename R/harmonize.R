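#' Allocation ratios of county fertilizer consumption across crops
#'
#' For each county-year and fertilizer kind, the share of the county's
#' total consumption attributed to crop i is
#' `ratio_i = FR_province(i) * A_county(i) / sum_i FR_province(i) * A_county(i)`:
#' the provincial crop-specific rates define the relative intensity, the
#' county's own areas the weights. The ratios of a defined key sum to one,
#' which is what makes the subsequent allocation mass-conserving.
#'
#' Edge policies: a county-year with any missing area is flagged
#' `"missing"` (no ratios); a zero denominator (no fertilized area) is
#' flagged `"undefined"`; a county whose province has no defined
#' other-crops rate while the county has other-crops area falls back to
#' allocating over the three named crops only, flagged `"no_other_rate"`
#' (the other category then receives no allocation).
#'
#' @param prov_rates four-crop provincial rate table (with flags) from
#'   [other_crops_rate()] or [provincial_stage()].
#' @param county_stats county statistics table, normally gap-filled
#'   ([gap_fill_county()]).
#' @return long data frame `county, province, year, kind, crop, ratio,
#'   flag`.
#' @export
allocation_ratios <- function(prov_rates, county_stats) {
  validate_provincial_rates(prov_rates, allow_other = TRUE)
  validate_county_stats(county_stats)
  cs <- county_stats
  unknown <- setdiff(unique(cs$province), unique(prov_rates$province))
  if (length(unknown)) {
    stop("county with unknown province: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  crops <- crop_categories()
  A <- cbind(cs$area_rice, cs$area_wheat, cs$area_maize, cs$area_other)
  src_cols <- paste0(c("fc_phosphorus", "fc_component", "area_rice",
                       "area_wheat", "area_maize", "area_total"), "_src")
  has_src <- all(src_cols %in% names(cs))
  filled_row <- if (has_src) {
    Reduce(`|`, lapply(src_cols, function(sc) cs[[sc]] == "gap_filled"))
  } else rep(FALSE, nrow(cs))

  out <- vector("list", length(fertilizer_kinds()))
  for (ki in seq_along(fertilizer_kinds())) {
    kind <- fertilizer_kinds()[ki]
    sub <- prov_rates[prov_rates$kind == kind, ]
    if ("flag" %in% names(sub)) sub$rate[sub$flag == "undefined"] <- NA_real_
    py <- paste(cs$province, cs$year)
    r <- vapply(crops, function(cr) {
      sub$rate[match(paste(py, cr), paste(sub$province, sub$year, sub$crop))]
    }, numeric(nrow(cs)))
    r <- matrix(r, nrow = nrow(cs))

    missing_area <- apply(A, 1, anyNA)
    bad <- !missing_area & is.na(r[, 1:3]) & A[, 1:3] > 0
    if (any(bad)) {
      stop("province lacks a named-crop rate for a county with positive ",
           "growing area (", sum(bad), " case(s))", call. = FALSE)
    }
    no_other <- !missing_area & is.na(r[, 4]) & A[, 4] > 0

    terms <- r * A
    terms[!is.na(A) & A == 0] <- 0        # absent category: zero weight
    terms[no_other, 4] <- 0               # fall back to named crops
    denom <- rowSums(terms)
    ratio <- terms / denom                # NaN where denom == 0
    undef <- !missing_area & denom == 0
    ratio[undef | missing_area, ] <- NA_real_

    key_flag <- ifelse(missing_area, "missing",
                       ifelse(undef, "undefined",
                              ifelse(filled_row, "gap_filled", "derived")))
    flag <- matrix(rep(key_flag, 4), ncol = 4)
    flag[no_other & !undef, 4] <- "no_other_rate"
    ratio[no_other & !undef, 4] <- NA_real_

    out[[ki]] <- data.frame(
      county = rep(cs$county, 4), province = rep(cs$province, 4),
      year = rep(cs$year, 4), kind = kind,
      crop = rep(crops, each = nrow(cs)),
      ratio = as.vector(ratio), flag = as.vector(flag),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$county, res$year, res$kind,
                   match(res$crop, crops)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Allocate county total consumption across crops
#'
#' Multiplies each allocation ratio by the county's total consumption of
#' that kind: `FC_i = ratio_i * FC_total`. Because ratios of a defined key
#' sum to one, the crop-specific consumptions sum back to the county
#' total.
#'
#' @param ratios from [allocation_ratios()].
#' @param county_stats the county statistics table (for the totals).
#' @return long data frame `county, province, year, kind, crop,
#'   consumption, flag` (g).
#' @export
allocate_consumption <- function(ratios, county_stats) {
  cs <- county_stats
  i <- match(paste(ratios$county, ratios$year),
             paste(cs$county, cs$year))
  if (anyNA(i)) stop("ratio/total key mismatch", call. = FALSE)
  fc <- ifelse(ratios$kind == "phosphorus", cs$fc_phosphorus[i],
               cs$fc_component[i])
  out <- ratios
  out$consumption <- out$ratio * fc
  out$flag[is.na(fc) & !is.na(out$ratio)] <- "missing"
  out$ratio <- NULL
  out
}

#' County crop-specific fertilizer rates
#'
#' Divides the allocated crop-specific consumption by the county's
#' crop-specific growing area: `FR_i = FC_i / A_i`. A zero area with zero
#' consumption yields an undefined (NA) rate, flagged — never a 0/0 NaN.
#' A zero area with positive consumption signals inconsistent upstream
#' tables and is an error.
#'
#' @param consumption from [allocate_consumption()].
#' @param county_stats the county statistics table (for the areas).
#' @return a county rate table: one row per county-year-crop with per-kind
#'   rates and provenance flags (see [validate_county_rates()]).
#' @export
county_rates <- function(consumption, county_stats) {
  cs <- county_stats
  area_col <- c(rice = "area_rice", wheat = "area_wheat",
                maize = "area_maize", other = "area_other")
  i <- match(paste(consumption$county, consumption$year),
             paste(cs$county, cs$year))
  if (anyNA(i)) stop("consumption/area key mismatch", call. = FALSE)
  A <- vapply(seq_len(nrow(consumption)), function(r) {
    cs[[area_col[[consumption$crop[r]]]]][i[r]]
  }, numeric(1))
  cons <- consumption$consumption
  bad <- !is.na(A) & A == 0 & !is.na(cons) & cons > 0
  if (any(bad)) {
    stop("positive consumption over zero growing area for ", sum(bad),
         " record(s): inconsistent upstream tables", call. = FALSE)
  }
  rate <- ifelse(!is.na(A) & A > 0, cons / A, NA_real_)
  flag <- consumption$flag
  flag[!is.na(A) & A == 0] <- "undefined"
  flag[is.na(rate) & flag %in% c("derived", "gap_filled")] <- "missing"

  long <- data.frame(county = consumption$county,
                     province = consumption$province,
                     year = consumption$year, crop = consumption$crop,
                     kind = consumption$kind, rate = rate, flag = flag,
                     stringsAsFactors = FALSE)
  base <- unique(long[c("county", "province", "year", "crop")])
  k <- paste(base$county, base$year, base$crop)
  pick <- function(kind_lab, what) {
    sub <- long[long$kind == kind_lab, ]
    sub[[what]][match(k, paste(sub$county, sub$year, sub$crop))]
  }
  out <- data.frame(
    county = base$county, province = base$province, year = base$year,
    crop = base$crop,
    rate_phosphorus = pick("phosphorus", "rate"),
    flag_phosphorus = pick("phosphorus", "flag"),
    rate_component = pick("component", "rate"),
    flag_component = pick("component", "flag"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$county, out$year,
                   match(out$crop, crop_categories())), , drop = FALSE]
  rownames(out) <- NULL
  validate_county_rates(out)
  out
}

#' Run the whole county-harmonization stage
#'
#' Gap-fills the county statistics, computes allocation ratios from the
#' four-crop provincial rates, allocates county totals, derives county
#' crop-specific rates per kind, and sums the two kinds into the combined
#' P2O5 rate.
#'
#' @param prov_rates four-crop provincial rate table (from
#'   [provincial_stage()]).
#' @param county_stats county statistics table.
#' @param policy a [gap_fill_policy()].
#' @param weights a [composition_weights()] table.
#' @return list with `rates` (county rate table incl. `p2o5_rate`),
#'   `ratios`, `consumption` and `county_filled` (the gap-filled
#'   statistics).
#' @export
harmonize_counties <- function(prov_rates, county_stats,
                               policy = gap_fill_policy(),
                               weights = composition_weights()) {
  filled <- gap_fill_county(county_stats, policy)
  ratios <- allocation_ratios(prov_rates, filled)
  cons <- allocate_consumption(ratios, filled)
  rates <- county_rates(cons, filled)
  rates <- total_p2o5_rate(rates, weights)
  list(rates = rates, ratios = ratios, consumption = cons,
       county_filled = filled)
}
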