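#' Mixing-derived damping strength
#'
#' Converts a cell's total mixing power (tidal plus wind) into the
#' fractional damping of thermal anomalies the generator applies there.
#' The response is logistic in mixing power: weakly mixed cells are
#' essentially undamped, strongly mixed cells approach `damping_max`.
#'
#' @param mixing_power Total mixing energy flux per cell, W/m^2.
#' @param damping_max Maximum fractional damping (default 0.75).
#' @param midpoint Mixing power at half damping, W/m^2 (default 0.05).
#' @param scale Logistic width, W/m^2 (default 0.02).
#' @return Damping strength in `[0, damping_max)` per cell.
#' @export
mixing_damping_strength <- function(mixing_power, damping_max = 0.75,
                                    midpoint = 0.05, scale = 0.02) {
  damping_max * stats::plogis((mixing_power - midpoint) / scale)
}

#' Generate daily SST for one ensemble member
#'
#' Simulates gap-free daily sea-surface temperature on the masked-in cells
#' of a reef grid: a latitude-dependent seasonal harmonic peaking in late
#' January (period 365.25 days), a scenario warming trend (the global
#' trajectory scaled by `local_warming_ratio`), AR(1) weather noise with a
#' shared regional component, and Poisson-timed summer heatwave pulses.
#' Noise and pulses at each cell are multiplied by a damping factor that
#' decreases with the cell's tidal-plus-wind mixing power — the planted
#' refugia mechanism — and that protection weakens linearly with global
#' warming, vanishing at `failure_warming` and reversing beyond it (the
#' planted refugia-failure threshold).
#'
#' @param grid A `reef_grid`.
#' @param forcing A `reef_forcing` built on the same grid; its daily
#'   calendar must cover the scenario years.
#' @param scenario A `scenario_spec`.
#' @return An object of class `daily_sst`: `sst` matrix (days x cells),
#'   `dates`, `damping_strength` per cell, and provenance
#'   (`model_id`, `scenario_id`, `seed`).
#' @examples
#' g <- generate_grid(resolution = 1, seed = 1)
#' f <- generate_forcing(g, years = 2000:2001, seed = 1)
#' s <- scenario_spec("SSP5-8.5", years = 2000:2001, seed = 1)
#' x <- generate_daily_sst(g, f, s)
#' dim(x$sst)
#' @export
generate_daily_sst <- function(grid, forcing, scenario) {
  stopifnot(inherits(grid, "reef_grid"), inherits(forcing, "reef_forcing"),
            inherits(scenario, "scenario_spec"))
  if (!identical(forcing$grid_signature, grid_signature(grid))) {
    stop("forcing and grid are on different cells", call. = FALSE)
  }
  dates <- daily_dates(scenario$years)
  if (min(dates) < min(forcing$dates) || max(dates) > max(forcing$dates)) {
    stop(sprintf(
      "calendar mismatch: forcing covers %s..%s but scenario requests %s..%s",
      min(forcing$dates), max(forcing$dates), min(dates), max(dates)
    ), call. = FALSE)
  }
  nd <- length(dates)
  nc <- n_cells(grid)
  lat <- grid$cells$lat

  # Deterministic skeleton: seasonal harmonic + local warming trend.
  tfrac <- as.numeric(dates - as.Date("1950-01-01")) / 365.25
  mean_sst <- 26.5 + 0.25 * (lat + 20)          # ~29 degC north, ~24 south
  amp <- 2.2 + 0.065 * (-lat - 10)              # larger seasonal cycle south
  seasonal <- outer(cos(2 * pi * (tfrac - 26 / 365.25)), amp) +
    matrix(mean_sst, nd, nc, byrow = TRUE)
  warming <- warming_path(scenario, decimal_year(dates))
  trend <- scenario$local_warming_ratio * warming

  # Mixing protection, two planted channels that both vanish at the
  # failure warming level W*:
  #  - trend suppression: mixing holds back local warming (relative to
  #    the climatology-centre epoch, so the recentred baseline is
  #    unaffected); the suppression is quadratic in warming with roots at
  #    the centre-epoch warming and at W*, collapsing - then reversing -
  #    as stratification fails;
  #  - anomaly damping: weather noise and heatwave pulses are scaled
  #    down in well-mixed cells, with the damping relaxing linearly in
  #    warming and reversing beyond W*.
  power <- tidal_power(forcing$u0, rho = forcing$rho)$p_tide +
    wind_mixing(forcing$wind_mean_cell, grid$cells$depth,
                rho_a = forcing$rho_a)$phi_wind_rate
  s_cell <- mixing_damping_strength(power, damping_max = scenario$damping_max)
  damp <- 1 - outer(1 - warming / scenario$failure_warming, s_cell)
  w_centre <- warming_path(scenario, 1988.2857)
  wf <- scenario$failure_warming
  shape <- if (wf > w_centre) {
    pmax((warming - w_centre) * (wf - warming) / ((wf - w_centre) / 2)^2,
         -1.5)
  } else {
    rep(0, nd)
  }
  protection <- scenario$protection_cooling * outer(shape, s_cell)

  anomaly <- matrix(0, nd, nc)
  if (scenario$noise_sd > 0 || scenario$heatwave_rate > 0) {
    anomaly <- with_seed(derive_seed(scenario$seed, 303L), {
      a <- matrix(0, nd, nc)
      if (scenario$noise_sd > 0) {
        innov_sd <- scenario$noise_sd * sqrt(1 - scenario$ar1^2)
        shared <- as.numeric(stats::filter(stats::rnorm(nd, 0, innov_sd),
                                           scenario$ar1, method = "recursive"))
        local <- matrix(stats::rnorm(nd * nc, 0, innov_sd), nd, nc)
        local <- apply(local, 2, function(z) {
          as.numeric(stats::filter(z, scenario$ar1, method = "recursive"))
        })
        a <- a + sqrt(0.4) * shared + sqrt(0.6) * local
      }
      if (scenario$heatwave_rate > 0) {
        n_years <- length(scenario$years)
        n_events <- stats::rpois(1, scenario$heatwave_rate * n_years)
        summer_ok <- as.integer(format(dates, "%m")) %in% c(11L, 12L, 1L, 2L, 3L)
        summer_idx <- which(summer_ok)
        nlat <- length(grid$lat); nlon <- length(grid$lon)
        ij <- cbind(grid$cells$row, grid$cells$col)
        hw <- matrix(0, nd, nc)
        for (e in seq_len(n_events)) {
          start <- sample(summer_idx, 1)
          dur <- round(stats::runif(1, scenario$heatwave_duration[1],
                                    scenario$heatwave_duration[2]))
          ampl <- stats::rlnorm(1, log(scenario$heatwave_amp),
                                scenario$heatwave_sdlog)
          env <- 0.35 + 0.65 * smooth_field(nlat, nlon,
                                            wavelength = max(4, min(nlat, nlon) / 2))[ij]
          idx <- start:min(start + dur - 1, nd)
          shape <- sin(pi * (seq_along(idx) - 0.5) / dur)
          hw[idx, ] <- hw[idx, ] + ampl * outer(shape, env)
        }
        # centre the pulse field on its per-cell day-of-year mean: the
        # expected seasonal heatwave load belongs to the climatology, so
        # anomalies stay zero-mean and the monthly-mean baseline (hence
        # the MMM) is statistically identical across damped and undamped
        # cells
        doy <- format(dates, "%m-%d")
        hw_clim <- rowsum(hw, doy) / as.integer(table(doy))
        a <- a + hw - hw_clim[doy, , drop = FALSE]
      }
      a
    })
  }

  sst <- seasonal + outer(trend, rep(1, nc)) - protection + damp * anomaly
  dimnames(sst) <- NULL
  structure(
    list(sst = sst,
         dates = dates,
         damping_strength = s_cell,
         model_id = scenario$model_id, scenario_id = scenario$scenario_id,
         seed = scenario$seed, grid_signature = grid_signature(grid)),
    class = "daily_sst"
  )
}

#' @export
print.daily_sst <- function(x, ...) {
  cat(sprintf(
    "<daily_sst> %s / %s: %d days (%s..%s) x %d cells\n",
    x$model_id, x$scenario_id, length(x$dates),
    min(x$dates), max(x$dates), ncol(x$sst)
  ))
  invisible(x)
}

#' Generate a global-mean surface air temperature series
#'
#' Annual global-mean `tas` for one scenario, 1860-2100: the deterministic
#' warming trajectory (anchored so the 2100 anomaly over the 1860-1880
#' baseline equals `warming_2100` exactly) plus small interannual noise.
#'
#' @param scenario A `scenario_spec`.
#' @param noise_sd Interannual noise standard deviation, degC
#'   (default 0.08; set 0 for the deterministic path).
#' @param years Years covered (default 1860:2100).
#' @return A data frame of class `global_tas` with columns `year`, `tas`.
#' @export
generate_global_tas <- function(scenario, noise_sd = 0.08,
                                years = 1860:2100) {
  stopifnot(inherits(scenario, "scenario_spec"))
  tas <- 13.9 + warming_path(scenario, years)
  if (noise_sd > 0) {
    tas <- tas + with_seed(derive_seed(scenario$seed, 404L),
                           stats::rnorm(length(years), 0, noise_sd))
  }
  structure(data.frame(year = years, tas = tas),
            class = c("global_tas", "data.frame"))
}

#' Generate a multi-model, multi-scenario synthetic ensemble
#'
#' Builds one `daily_sst` and matching `global_tas` per (pseudo-model,
#' scenario) pair. Models differ by perturbations of end-of-century
#' warming, local warming ratio, noise amplitude and heatwave timing;
#' with `perturbation = 0` all models are identical.
#'
#' @param grid A `reef_grid`.
#' @param forcing A `reef_forcing` on the same grid.
#' @param scenarios Character vector of scenario ids (default all four).
#' @param n_models Number of pseudo-models (default 5).
#' @param model_ids Distinct model labels (default `"M1"`..).
#' @param perturbation Relative scale of inter-model perturbations
#'   (default 0.06).
#' @param years Years of daily SST per member.
#' @param seed Base seed.
#' @param ... Further arguments passed to [scenario_spec()] for every
#'   member (e.g. `failure_warming`, `noise_sd`).
#' @return A list of class `reef_ensemble`; each element has `sst`
#'   (`daily_sst`), `tas` (`global_tas`), `model_id`, `scenario_id`.
#' @export
generate_ensemble <- function(grid, forcing,
                              scenarios = c("SSP1-1.9", "SSP1-2.6",
                                            "SSP3-7.0", "SSP5-8.5"),
                              n_models = 5L,
                              model_ids = paste0("M", seq_len(n_models)),
                              perturbation = 0.06,
                              years = 1950:2100,
                              seed = 1L, ...) {
  stopifnot(n_models >= 1L)
  if (anyDuplicated(model_ids)) {
    stop("duplicate model_ids", call. = FALSE)
  }
  stopifnot(length(model_ids) == n_models)
  pert <- with_seed(derive_seed(seed, 505L), {
    list(warm = stats::rnorm(n_models, 0, 1),
         ratio = stats::rnorm(n_models, 0, 1),
         noise = stats::rnorm(n_models, 0, 1))
  })
  members <- list()
  for (s in scenarios) {
    base <- scenario_spec(s, years = years, seed = seed, ...)
    for (m in seq_len(n_models)) {
      spec <- base
      spec$model_id <- model_ids[m]
      spec$warming_2100 <- base$warming_2100 * (1 + perturbation * pert$warm[m])
      spec$local_warming_ratio <- base$local_warming_ratio *
        (1 + 0.5 * perturbation * pert$ratio[m])
      spec$noise_sd <- base$noise_sd * exp(perturbation * pert$noise[m])
      spec$seed <- if (perturbation == 0) seed else derive_seed(seed, 1000L + m)
      members[[paste(s, model_ids[m], sep = "/")]] <- list(
        sst = generate_daily_sst(grid, forcing, spec),
        tas = generate_global_tas(spec),
        model_id = model_ids[m],
        scenario_id = s
      )
    }
  }
  structure(members, class = "reef_ensemble")
}

#' @export
print.reef_ensemble <- function(x, ...) {
  cat(sprintf("<reef_ensemble> %d members: %s\n", length(x),
              paste(utils::head(names(x), 8), collapse = ", ")))
  invisible(x)
}
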