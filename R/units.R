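#' Unit conversion to and from canonical units
#'
#' All tables are held internally in canonical units: grams for mass,
#' square metres for area, grams per square metre for application rates
#' (g P2O5 m^-2 once converted). Statistical yearbooks publish in a mix of
#' tonnes, thousand hectares, kg/ha and kg/mu; readers convert on load and
#' the conversion is exactly invertible.
#'
#' Supported labels: mass `g`, `kg`, `t`; area `m2`, `ha`, `km2`, `khm2`
#' (thousand hectares); rate `g_per_m2`, `kg_per_ha`, `kg_per_mu`
#' (1 mu = 1/15 ha exactly, so 1 kg/mu = 1.5 g/m^2), `t_per_km2`.
#'
#' @param x numeric vector of values.
#' @param unit unit label the values are expressed in.
#' @param quantity one of `"mass"`, `"area"`, `"rate"`.
#' @return `convert_unit()` returns the values in the canonical unit;
#'   `revert_unit()` expresses canonical values back in `unit`.
#' @examples
#' convert_unit(65, "kg_per_ha", "rate")   # 6.5 g/m^2
#' revert_unit(6.5, "kg_per_ha", "rate")   # 65
#' @export
convert_unit <- function(x, unit, quantity) {
  x * .unit_factor(unit, quantity)
}

#' @rdname convert_unit
#' @export
revert_unit <- function(x, unit, quantity) {
  x / .unit_factor(unit, quantity)
}

.mass_to_g <- c(g = 1, kg = 1e3, t = 1e6)
.area_to_m2 <- c(m2 = 1, ha = 1e4, km2 = 1e6, khm2 = 1e7)
.rate_to_gm2 <- c(g_per_m2 = 1, kg_per_ha = 0.1, kg_per_mu = 1.5, t_per_km2 = 1)

.unit_factor <- function(unit, quantity) {
  stopifnot(length(unit) == 1L, length(quantity) == 1L)
  tab <- switch(quantity,
    mass = .mass_to_g,
    area = .area_to_m2,
    rate = .rate_to_gm2,
    stop("unknown quantity '", quantity, "' (use mass/area/rate)", call. = FALSE)
  )
  if (!unit %in% names(tab)) {
    stop("unknown ", quantity, " unit label '", unit, "'; known: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  unname(tab[unit])
}
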