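# Report figures: plate-carree tile maps of per-cell fields, flux
# violins by group, and difference-vs-warming trajectories.

cell_df <- function(grid, values, name = "value") {
  df <- grid$cells[, c("lon", "lat")]
  df[[name]] <- values
  df
}

#' Map a per-cell field
#'
#' @param grid A `reef_grid`.
#' @param values Per-cell numeric vector.
#' @param title Plot title.
#' @param legend Legend label.
#' @return A ggplot object.
#' @export
plot_field_map <- function(grid, values, title = NULL, legend = "value") {
  df <- cell_df(grid, values)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_tile(width = grid$resolution, height = grid$resolution) +
    ggplot2::scale_fill_viridis_c(name = legend) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "Longitude (deg E)",
                  y = "Latitude (deg N)") +
    ggplot2::theme_minimal()
}

#' Map of multi-model refugia agreement
#'
#' @param agreement An `agreement_map`.
#' @param grid The matching `reef_grid`.
#' @return A ggplot object.
#' @export
plot_agreement_map <- function(agreement, grid) {
  df <- cell_df(grid, factor(agreement$n_agree,
                             levels = 0:agreement$n_models), "agree")
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$agree)) +
    ggplot2::geom_tile(width = grid$resolution, height = grid$resolution) +
    ggplot2::scale_fill_viridis_d(name = "models\nagreeing", drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Refugia model agreement",
                  x = "Longitude (deg E)", y = "Latitude (deg N)") +
    ggplot2::theme_minimal()
}

#' Violin comparison of mixing fluxes in refugia vs non-refugia
#'
#' @param p_tide Per-cell tidal power, W/m^2.
#' @param wind_flux Per-cell summer-mean wind mixing flux.
#' @param mask A `refugia_mask`.
#' @return A ggplot object.
#' @export
plot_flux_comparison <- function(p_tide, wind_flux, mask) {
  grp <- ifelse(mask$is_refugium, "refugia", "non-refugia")
  df <- rbind(
    data.frame(group = grp, flux = as.numeric(p_tide), kind = "tidal"),
    data.frame(group = grp, flux = as.numeric(wind_flux), kind = "wind")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$flux,
                                   fill = .data$group)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Mixing energy flux (W m-2)") +
    ggplot2::theme_minimal()
}

#' Smoothed DHW-difference trajectory for one scenario
#'
#' @param trajectory Data frame with `year`, `diff`, `diff_smooth`.
#' @param scenario_id Label for the title.
#' @return A ggplot object.
#' @export
plot_diff_trajectory <- function(trajectory, scenario_id = NULL) {
  ggplot2::ggplot(trajectory, ggplot2::aes(.data$year, .data$diff)) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$diff_smooth), colour = "firebrick",
                       na.rm = TRUE, linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(title = scenario_id, x = "Year",
                  y = "Non-refugia - refugia DHW (degC-weeks)") +
    ggplot2::theme_minimal()
}

#' Fitted difference-vs-warming curve with its standard-error band
#'
#' @param fit A `quadratic_fit`.
#' @param pairs The (warming, diff) pairs the fit used.
#' @return A ggplot object.
#' @export
plot_diff_vs_warming <- function(fit, pairs) {
  wseq <- seq(fit$warming_range[1], fit$warming_range[2], length.out = 200)
  band <- predict(fit, wseq)
  p <- ggplot2::ggplot(pairs, ggplot2::aes(.data$warming, .data$diff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$warming,
                                      ymin = .data$fit - .data$se,
                                      ymax = .data$fit + .data$se),
                         inherit.aes = FALSE, alpha = 0.3) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(.data$warming, .data$fit),
                       inherit.aes = FALSE, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Global warming above 1860-1880 (degC)",
                  y = "Non-refugia - refugia DHW (degC-weeks)") +
    ggplot2::theme_minimal()
  if (!is.na(fit$crossing)) {
    p <- p + ggplot2::geom_vline(xintercept = fit$crossing, linetype = 3)
  }
  p
}

#' Map of relative warming slopes over refugia cells
#'
#' @param slopes A `slope_field`.
#' @param grid The matching `reef_grid`.
#' @return A ggplot object.
#' @export
plot_slope_map <- function(slopes, grid) {
  vals <- rep(NA_real_, n_cells(grid))
  vals[slopes$cell] <- slopes$slope
  df <- cell_df(grid, vals)
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_tile(width = grid$resolution, height = grid$resolution) +
    ggplot2::scale_fill_gradient2(name = "slope\n(degC-wk/yr)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Relative warming of refugia cells",
                  x = "Longitude (deg E)", y = "Latitude (deg N)") +
    ggplot2::theme_minimal()
}

#' Map of percentage change of an atmospheric field
#'
#' @param pct Per-cell percentage change.
#' @param grid The matching `reef_grid`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_change_map <- function(pct, grid, title = "Change (%)") {
  df <- cell_df(grid, pct)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_tile(width = grid$resolution, height = grid$resolution) +
    ggplot2::scale_fill_gradient2(name = "%") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "Longitude (deg E)",
                  y = "Latitude (deg N)") +
    ggplot2::theme_minimal()
}
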