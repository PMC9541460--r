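# End-to-end orchestration: simulate -> climatology -> DHW -> refugia ->
# energy flux -> trends, with every stage's outputs written beside a
# machine-readable summary carrying provenance (seed, config hash,
# package version).

#' Build a pipeline configuration
#'
#' A declarative nested list of every tunable in the pipeline, with the
#' study-condition defaults; any element can be overridden via `...`
#' (e.g. `grid = list(resolution = 1)` merges into the grid block).
#'
#' @param ... Named blocks or scalar overrides merged over the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    years = 1950:2100,
    scenarios = c("SSP1-1.9", "SSP1-2.6", "SSP3-7.0", "SSP5-8.5"),
    n_models = 5L,
    perturbation = 0.06,
    include_tas = TRUE,
    grid = list(resolution = 0.1),
    forcing = list(mixing_contrast = 0.5, dipole = TRUE),
    scenario = list(),                    # extra scenario_spec arguments
    climatology = list(years = 1985:2012, centre_year = 1988.2857),
    dhw = list(window_days = 84L, hotspot_floor = 1, weekly_divisor = 7),
    refugia = list(percentile = 0.2, period = 1999:2019, min_models = 2L),
    flux = list(bleaching_years = c(2002, 2016, 2017),
                months = c(12L, 1L, 2L, 3L), delta = 0.023,
                n_boot = 500L, block_size = 5L),
    trends = list(window = 11L, aggregate = "median",
                  slope_scenario = "SSP5-8.5", slope_period = 2014:2100,
                  present = 1999:2019, future = 2050:2100,
                  bleach_threshold = 2),
    make_figures = FALSE
  )
  over <- list(...)
  for (k in names(over)) {
    if (is.list(cfg[[k]]) && is.list(over[[k]])) {
      cfg[[k]] <- utils::modifyList(cfg[[k]], over[[k]])
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Declarative key-value configuration: top-level keys and nested blocks
#' mirror [pipeline_config()] arguments and are merged over the
#' defaults, so a file needs to state only what it overrides.
#'
#' @param path YAML file path. Year ranges may be written as strings
#'   like `"1999:2019"`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  expand_ranges <- function(x) {
    if (is.list(x)) return(lapply(x, expand_ranges))
    if (is.character(x) && length(x) == 1L &&
        grepl("^-?[0-9]+:-?[0-9]+$", x)) {
      ends <- as.integer(strsplit(x, ":")[[1]])
      return(seq(ends[1], ends[2]))
    }
    x
  }
  do.call(pipeline_config, expand_ranges(yaml::read_yaml(path)))
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full refugia pipeline
#'
#' Executes simulate, climatology, DHW, refugia, energy-flux and trends
#' stages on a synthetic ensemble and writes CSV outputs plus a JSON
#' summary (refugia fraction, per-scenario warming-level crossings, flux
#' differences) to `out_dir`. Re-running with the same configuration and
#' seed reproduces the outputs exactly.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- run_stage("simulate", {
    grid <- do.call(generate_grid, c(config$grid, list(seed = config$seed)))
    forcing <- do.call(generate_forcing, c(
      list(grid = grid, years = config$years, seed = config$seed),
      config$forcing
    ))
    ens <- do.call(generate_ensemble, c(
      list(grid = grid, forcing = forcing, scenarios = config$scenarios,
           n_models = config$n_models, perturbation = config$perturbation,
           years = config$years, seed = config$seed),
      config$scenario
    ))
    if (!config$include_tas) {
      ens <- lapply(ens, function(m) { m$tas <- NULL; m })
    }
    list(grid = grid, forcing = forcing, ensemble = ens)
  })
  grid <- sim$grid

  annmax <- run_stage("climatology+dhw", {
    lapply(sim$ensemble, function(member) {
      clim <- mmm_climatology(member$sst,
                              years = config$climatology$years,
                              centre_year = config$climatology$centre_year)
      d <- dhw(hotspot(member$sst, clim),
               window_days = config$dhw$window_days,
               hotspot_floor = config$dhw$hotspot_floor,
               weekly_divisor = config$dhw$weekly_divisor)
      suppressWarnings(annual_max_dhw(d))
    })
  })

  ref <- run_stage("refugia", {
    masks <- lapply(annmax, function(am) {
      classify_refugia(climatological_mean_dhw(am, config$refugia$period),
                       percentile = config$refugia$percentile,
                       period = range(config$refugia$period))
    })
    agreement <- lapply(config$scenarios, function(s) {
      model_agreement(masks[grepl(paste0("^", s, "/"), names(masks))])
    })
    names(agreement) <- config$scenarios
    list(masks = masks, agreement = agreement)
  })

  flux <- run_stage("flux", {
    p_tide <- tidal_power(sim$forcing$u0, rho = sim$forcing$rho)$p_tide
    wflux_daily <- wind_mixing(sim$forcing$wind_speed, grid$cells$depth,
                               delta = config$flux$delta,
                               rho_a = sim$forcing$rho_a)$phi_wind_rate
    wflux <- summer_flux_mean(wflux_daily, sim$forcing$dates,
                              years = config$flux$bleaching_years,
                              months = config$flux$months)
    flux_scenario <- config$scenarios[1]
    scen_masks <- ref$masks[grepl(paste0("^", flux_scenario, "/"),
                                  names(ref$masks))]
    per_model <- lapply(scen_masks, function(m) {
      list(
        tidal = compare_groups(p_tide, m, grid, n_boot = config$flux$n_boot,
                               block_size = config$flux$block_size,
                               seed = config$seed),
        wind = compare_groups(wflux, m, grid, n_boot = config$flux$n_boot,
                              block_size = config$flux$block_size,
                              seed = config$seed)
      )
    })
    list(per_model = per_model, scenario = flux_scenario,
         p_tide = p_tide, wind_flux = wflux)
  })

  trend <- run_stage("trends", {
    if (!config$include_tas ||
        any(vapply(sim$ensemble, function(m) is.null(m$tas), logical(1)))) {
      stop("global temperature series missing from ensemble members")
    }
    scen_results <- lapply(config$scenarios, function(s) {
      keys <- names(annmax)[grepl(paste0("^", s, "/"), names(annmax))]
      pairs <- do.call(rbind, lapply(keys, function(k) {
        dd <- dhw_difference(annmax[[k]], ref$masks[[k]],
                             aggregate = config$trends$aggregate)
        an <- warming_anomaly(sim$ensemble[[k]]$tas)
        merge(dd, an, by = "year")
      }))
      names(pairs)[names(pairs) == "anomaly"] <- "warming"
      fit <- fit_diff_vs_warming(pairs)
      # ensemble-mean smoothed trajectory
      diffs <- lapply(keys, function(k) {
        dhw_difference(annmax[[k]], ref$masks[[k]],
                       aggregate = config$trends$aggregate)
      })
      years <- Reduce(intersect, lapply(diffs, `[[`, "year"))
      mean_diff <- rowMeans(vapply(diffs, function(d) {
        d$diff[match(years, d$year)]
      }, numeric(length(years))))
      list(fit = fit,
           trajectory = data.frame(
             year = years, diff = mean_diff,
             diff_smooth = rolling_mean(mean_diff, config$trends$window)
           ))
    })
    names(scen_results) <- config$scenarios
    # relative warming slopes + bleaching-era atmospheric change under the
    # highest-forcing scenario available
    ss <- config$trends$slope_scenario
    out <- list(scenarios = scen_results)
    if (ss %in% config$scenarios) {
      keys <- names(annmax)[grepl(paste0("^", ss, "/"), names(annmax))]
      out$slopes <- lapply(keys, function(k) {
        relative_warming_slope(annmax[[k]], ref$masks[[k]],
                               period = config$trends$slope_period)
      })
      gm <- ensemble_median(lapply(annmax[keys], grid_median))
      bleach <- detect_bleaching_years(gm, config$trends$bleach_threshold)
      out$bleaching_years <- bleach
      out$atmos <- tryCatch(list(
        wind = atmos_change(sim$forcing$wind_speed, sim$forcing$dates,
                            bleach, config$trends$present,
                            config$trends$future),
        shortwave = atmos_change(sim$forcing$shortwave, sim$forcing$dates,
                                 bleach, config$trends$present,
                                 config$trends$future)
      ), error = function(e) conditionMessage(e))
    }
    out
  })

  summary <- run_stage("report", {
    refugia_fraction <- mean(vapply(ref$masks, function(m) {
      mean(m$is_refugium)
    }, numeric(1)))
    crossings <- lapply(trend$scenarios, function(s) {
      if (is.na(s$fit$crossing)) NULL else s$fit$crossing
    })
    flux_diff <- list(
      tidal = mean(vapply(flux$per_model, function(x) x$tidal$difference,
                          numeric(1))),
      wind = mean(vapply(flux$per_model, function(x) x$wind$difference,
                         numeric(1)))
    )
    cfg_plain <- unclass(config)
    summary <- list(
      package_version = as.character(utils::packageVersion("reefugia")),
      seed = config$seed,
      config_hash = rlang::hash(cfg_plain),
      n_members = length(sim$ensemble),
      n_cells = n_cells(grid),
      refugia_fraction = refugia_fraction,
      crossing_degC = crossings,
      flux_difference_refugia_minus_non = flux_diff,
      bleaching_years = trend$bleaching_years %||% integer(0)
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_grid_csv(grid, file.path(out_dir, "grid.csv"))
    for (s in config$scenarios) {
      traj <- trend$scenarios[[s]]$trajectory
      utils::write.csv(traj, file.path(out_dir, paste0(
        "diff_trajectory_", gsub("[^A-Za-z0-9]", "", s), ".csv"
      )), row.names = FALSE)
    }
    cross_df <- data.frame(
      scenario = names(trend$scenarios),
      crossing_degC = vapply(trend$scenarios, function(s) s$fit$crossing,
                             numeric(1))
    )
    utils::write.csv(cross_df, file.path(out_dir, "crossings.csv"),
                     row.names = FALSE)
    if (isTRUE(config$make_figures)) {
      save_pipeline_figures(out_dir, grid, ref, flux, trend)
    }
    summary
  })

  invisible(summary)
}

save_pipeline_figures <- function(out_dir, grid, ref, flux, trend) {
  ggsave_quiet <- function(name, plot) {
    suppressMessages(ggplot2::ggsave(file.path(out_dir, name), plot,
                                     width = 7, height = 5, dpi = 120))
  }
  first_scen <- names(ref$agreement)[1]
  ggsave_quiet("fig_agreement.png",
               plot_agreement_map(ref$agreement[[first_scen]], grid))
  first_mask <- ref$masks[[grep(paste0("^", flux$scenario, "/"),
                                names(ref$masks))[1]]]
  ggsave_quiet("fig_flux.png",
               plot_flux_comparison(flux$p_tide, flux$wind_flux, first_mask))
  for (s in names(trend$scenarios)) {
    ggsave_quiet(paste0("fig_diff_", gsub("[^A-Za-z0-9]", "", s), ".png"),
                 plot_diff_trajectory(trend$scenarios[[s]]$trajectory, s))
  }
  if (!is.null(trend$slopes)) {
    ggsave_quiet("fig_slope.png", plot_slope_map(trend$slopes[[1]], grid))
  }
  if (is.list(trend$atmos)) {
    ggsave_quiet("fig_atmos_wind.png",
                 plot_change_map(trend$atmos$wind, grid,
                                 "Wind speed change (%)"))
  }
  invisible(NULL)
}
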