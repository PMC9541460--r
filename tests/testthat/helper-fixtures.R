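# Shared fixtures and independent oracles, all built in code.

# Minimal daily_sst object with prescribed values (bypasses the generator
# so climatology/stress tests control their inputs exactly).
make_sst <- function(mat, dates, model_id = "TEST", scenario_id = "TEST") {
  structure(
    list(sst = mat, dates = dates, damping_strength = NULL,
         model_id = model_id, scenario_id = scenario_id,
         seed = 0L, grid_signature = NULL),
    class = "daily_sst"
  )
}

make_hotspot <- function(mat, dates) {
  structure(list(hotspot = mat, dates = dates), class = "hotspot_series")
}

make_dhw_series <- function(mat, dates) {
  structure(list(dhw = mat, dates = dates, window_days = 84L,
                 hotspot_floor = 1, weekly_divisor = 7),
            class = "dhw_series")
}

make_annual_max <- function(mat, years) {
  structure(list(annual_max = mat, years = years, convention = "austral"),
            class = "annual_max")
}

make_mask <- function(flags, threshold = NA_real_, percentile = 0.2) {
  structure(list(is_refugium = flags, threshold_value = threshold,
                 percentile = percentile, period = c(1999L, 2019L)),
            class = "refugia_mask")
}

# Brute-force DHW oracle: explicit O(n * window) re-summation.
naive_dhw <- function(hs_vec, window = 84L, floor = 1, divisor = 7) {
  n <- length(hs_vec)
  out <- rep(NA_real_, n)
  for (t in window:n) {
    w <- hs_vec[(t - window + 1L):t]
    out[t] <- sum(w[w >= floor]) / divisor
  }
  out
}

# Small grid + forcing + member used by several generator tests.
small_grid <- function(seed = 1, resolution = 2) {
  generate_grid(resolution = resolution, seed = seed)
}
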