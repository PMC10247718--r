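# small synthetic-world configurations used across the suite

tiny_config <- function(seed = 1, np = 2, cpp = c(3, 3), nrow = 12,
                        ncol = 12, missing_rate = 0,
                        flavor = "provincial_uniform", years = 2004:2016,
                        max_gap_run = 2) {
  world_config(n_provinces = np, counties_per_province = cpp, years = years,
               grid = list(nrow = nrow, ncol = ncol, px = 0.01,
                           xmin = 100, ymax = 40),
               missing_rate = missing_rate, max_gap_run = max_gap_run,
               flavor = flavor, seed = seed)
}

tiny_world <- function(...) generate_world(tiny_config(...))

max_rel_err <- function(got, want) {
  ok <- !is.na(got) & !is.na(want)
  if (!any(ok)) return(NA_real_)
  max(abs(got[ok] - want[ok]) / pmax(abs(want[ok]), 1e-300))
}
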