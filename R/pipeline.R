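#' Run the full harmonization pipeline on a set of tables
#'
#' Provincial stage (crop-specific consumption, residual other-crops
#' rate), county harmonization (gap-fill, allocation ratios, allocation,
#' county rates) and P2O5 summation, end to end.
#'
#' @param provincial_rates named-crop provincial rate table.
#' @param provincial_totals provincial totals table.
#' @param county_stats county statistics table.
#' @param policy a [gap_fill_policy()].
#' @param weights a [composition_weights()] table.
#' @return list with `provincial` (the [provincial_stage()] result) and
#'   the [harmonize_counties()] components (`rates`, `ratios`,
#'   `consumption`, `county_filled`).
#' @export
run_pipeline <- function(provincial_rates, provincial_totals, county_stats,
                         policy = gap_fill_policy(),
                         weights = composition_weights()) {
  prov <- provincial_stage(provincial_rates, provincial_totals)
  harm <- harmonize_counties(prov$rates, county_stats, policy = policy,
                             weights = weights)
  c(list(provincial = prov), harm)
}

#' Run the pipeline on a synthetic world
#'
#' Convenience wrapper passing a world's tables and composition weights
#' through [run_pipeline()].
#'
#' @param world a [generate_world()] world.
#' @param policy a [gap_fill_policy()].
#' @return see [run_pipeline()].
#' @export
run_pipeline_world <- function(world, policy = gap_fill_policy()) {
  stopifnot(inherits(world, "phos_world"))
  run_pipeline(world$provincial_rates, world$provincial_totals,
               world$county_stats, policy = policy,
               weights = world$weights)
}
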