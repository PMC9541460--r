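#' Scenario specification for the synthetic ensemble
#'
#' Bundles the parameters of one pseudo-model / emission-scenario member:
#' how much the world warms by 2100, the shape of the warming trajectory,
#' the daily weather-noise model, the marine-heatwave process, and the
#' warming level at which mixing protection fails. Default end-of-century
#' warming levels (1.4, 1.8, 3.8, 4.6 degC above 1860-1880 for SSP1-1.9,
#' SSP1-2.6, SSP3-7.0, SSP5-8.5) are synthetic conventions consistent with
#' low scenarios staying below 1.5/2 degC; they are not estimates from any
#' climate-model archive.
#'
#' @param scenario_id One of `"SSP1-1.9"`, `"SSP1-2.6"`, `"SSP3-7.0"`,
#'   `"SSP5-8.5"`.
#' @param model_id Pseudo-model label (default `"M1"`).
#' @param warming_2100 Global-mean warming at 2100 relative to the
#'   1860-1880 mean, degC. `NULL` picks the scenario default.
#' @param trend_shape `"smooth"` (accelerating, quadratic-in-time) or
#'   `"linear"`.
#' @param years Calendar years of daily SST output (default 1950:2100).
#' @param local_warming_ratio Ratio of local shelf SST warming to global
#'   near-surface warming (default 0.85; shelf seas track slightly below
#'   the global mean).
#' @param noise_sd Marginal standard deviation of the daily AR(1) SST
#'   anomaly, degC (default 0.35).
#' @param ar1 Lag-1 autocorrelation of the daily anomaly (default 0.8).
#' @param heatwave_rate Expected number of heatwave events per year
#'   (default 1.2; events are Poisson-timed in austral summer).
#' @param heatwave_amp Median event amplitude, degC (default 1.6,
#'   log-normal with `heatwave_sdlog`).
#' @param heatwave_sdlog Log-scale spread of event amplitudes (default 0.4).
#' @param heatwave_duration Range of event durations in days
#'   (default `c(10, 60)`).
#' @param failure_warming Global warming level (degC) at which the
#'   mixing-protection mechanism vanishes; beyond it, formerly protected
#'   cells see amplified extremes (default 3).
#' @param damping_max Maximum fractional damping of anomalies in the
#'   best-mixed cells at zero warming (default 0.75).
#' @param protection_cooling Peak trend suppression, degC per unit
#'   damping strength, of the mixing-protection channel (default 0.3):
#'   well-mixed cells warm more slowly than their neighbours until
#'   `failure_warming` is approached, then catch up and overshoot.
#' @param seed Integer seed for this member.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(scenario_id = c("SSP1-1.9", "SSP1-2.6",
                                          "SSP3-7.0", "SSP5-8.5"),
                          model_id = "M1",
                          warming_2100 = NULL,
                          trend_shape = c("smooth", "linear"),
                          years = 1950:2100,
                          local_warming_ratio = 0.85,
                          noise_sd = 0.35,
                          ar1 = 0.8,
                          heatwave_rate = 1.2,
                          heatwave_amp = 1.6,
                          heatwave_sdlog = 0.4,
                          heatwave_duration = c(10, 60),
                          failure_warming = 3,
                          damping_max = 0.75,
                          protection_cooling = 0.3,
                          seed = 1L) {
  scenario_id <- match.arg(scenario_id)
  trend_shape <- match.arg(trend_shape)
  defaults <- c("SSP1-1.9" = 1.4, "SSP1-2.6" = 1.8,
                "SSP3-7.0" = 3.8, "SSP5-8.5" = 4.6)
  if (is.null(warming_2100)) warming_2100 <- unname(defaults[scenario_id])
  stopifnot(warming_2100 >= 0, noise_sd >= 0, ar1 >= 0, ar1 < 1,
            heatwave_rate >= 0, failure_warming > 0,
            damping_max >= 0, damping_max < 1)
  structure(
    list(scenario_id = scenario_id, model_id = model_id,
         warming_2100 = warming_2100, trend_shape = trend_shape,
         years = years, local_warming_ratio = local_warming_ratio,
         noise_sd = noise_sd, ar1 = ar1,
         heatwave_rate = heatwave_rate, heatwave_amp = heatwave_amp,
         heatwave_sdlog = heatwave_sdlog,
         heatwave_duration = heatwave_duration,
         failure_warming = failure_warming, damping_max = damping_max,
         protection_cooling = protection_cooling, seed = seed),
    class = "scenario_spec"
  )
}

#' Deterministic global warming trajectory of a scenario
#'
#' The anomaly relative to the 1860-1880 mean implied by the scenario's
#' `trend_shape`, constructed so the 2100 anomaly equals `warming_2100`
#' exactly and the 1860-1880 mean anomaly is exactly zero.
#'
#' @param scenario A `scenario_spec`.
#' @param year Numeric vector of (possibly fractional) years.
#' @return Anomaly in degC for each `year`.
#' @export
warming_path <- function(scenario, year) {
  q <- switch(scenario$trend_shape,
    linear = function(y) y,
    smooth = function(y) pmax(y - 1860, 0)^3
  )
  base <- mean(q(1860:1880))
  scenario$warming_2100 * (q(year) - base) / (q(2100) - base)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %s / %s: +%.2f degC by 2100 (%s trend), years %d-%d, seed %d\n",
    x$scenario_id, x$model_id, x$warming_2100, x$trend_shape,
    min(x$years), max(x$years), x$seed
  ))
  invisible(x)
}
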