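# Mixing-energy fluxes in the Simpson-Hunter tradition: turbulent power
# from bottom tidal friction and the rate of working of the wind on
# water-column stratification. Both scale with the cube of their velocity
# argument; together they set how efficiently a shelf cell mixes surface
# heat downward.

#' Tidal mixing power
#'
#' `P_tide = 4 k_b rho u0^3 / (3 pi)`, the cycle-averaged turbulent power
#' per unit area generated by bottom friction under a tidal current of
#' amplitude `u0`.
#'
#' @param u0 Tidal current amplitude, m/s (vector or matrix; must be
#'   non-negative).
#' @param k_b Bottom drag coefficient (default 0.003).
#' @param rho Seawater density, kg/m^3 (default 1025).
#' @return A `tidal_power` object with `p_tide` (same shape as `u0`,
#'   W/m^2) and the parameters used.
#' @examples
#' tidal_power(0.5)$p_tide  # ~0.1631 W/m^2
#' @export
tidal_power <- function(u0, k_b = 0.003, rho = 1025) {
  if (any(u0 < 0, na.rm = TRUE)) {
    stop("`u0` must be non-negative", call. = FALSE)
  }
  structure(
    list(p_tide = 4 * k_b * rho * u0^3 / (3 * pi), k_b = k_b, rho = rho),
    class = "tidal_power"
  )
}

#' Wind mixing energy flux
#'
#' Magnitude of the wind-driven rate of change of the potential-energy
#' anomaly, `delta * k_s * rho_a * w^3 / h`: the stirring the wind does
#' per unit volume of a water column of depth `h`. (In stratification
#' budgets this term carries a negative sign — wind work erodes the
#' anomaly; the magnitude is reported here.)
#'
#' @param w Wind speed at 10 m, m/s (vector or matrix, non-negative).
#' @param h Total water depth, m (positive; recycled across rows when `w`
#'   is a days x cells matrix).
#' @param delta Mixing efficiency (default 0.023, a standard shelf-sea
#'   value; the quantity is linear in it, so rescaling is trivial).
#' @param k_s Surface drag coefficient times slippage factor
#'   (default 6.4e-5).
#' @param rho_a Air density, kg/m^3 (default 1.2).
#' @param depth_divide Divide by `h` (default `TRUE`); `FALSE` yields the
#'   depth-independent surface working rate `delta k_s rho_a w^3`.
#' @return A `wind_mixing` object with `phi_wind_rate` (same shape as
#'   `w`, W/m^2 per metre of depth when divided) and the parameters used.
#' @examples
#' wind_mixing(8, 20)$phi_wind_rate  # ~4.522e-5
#' @export
wind_mixing <- function(w, h, delta = 0.023, k_s = 6.4e-5, rho_a = 1.2,
                        depth_divide = TRUE) {
  if (any(w < 0, na.rm = TRUE)) stop("`w` must be non-negative", call. = FALSE)
  if (any(h <= 0, na.rm = TRUE)) stop("`h` must be positive", call. = FALSE)
  rate <- delta * k_s * rho_a * w^3
  if (depth_divide) {
    rate <- if (is.matrix(w)) sweep(rate, 2, h, `/`) else rate / h
  }
  structure(
    list(phi_wind_rate = rate, delta = delta, k_s = k_s, rho_a = rho_a,
         depth_divide = depth_divide),
    class = "wind_mixing"
  )
}

#' Austral-summer mean of a daily flux field
#'
#' Per-cell arithmetic mean over the December-March days of the listed
#' austral summer years (December belongs to the following year's
#' summer: summer 2002 spans Dec 2001 - Mar 2002). The default years are
#' the mass-bleaching summers 2002, 2016 and 2017.
#'
#' @param flux Daily field, days x cells matrix.
#' @param dates `Date` vector matching the rows of `flux`.
#' @param years Austral summer years to include
#'   (default `c(2002, 2016, 2017)`).
#' @param months Months of the summer season (default `c(12, 1, 2, 3)`).
#' @return Numeric vector: per-cell mean over the selected days.
#' @export
summer_flux_mean <- function(flux, dates, years = c(2002, 2016, 2017),
                             months = c(12L, 1L, 2L, 3L)) {
  stopifnot(is.matrix(flux), length(dates) == nrow(flux))
  mo <- as.integer(format(dates, "%m"))
  sel <- mo %in% months & austral_year(dates) %in% years
  if (!any(sel)) {
    stop("none of the requested summer days are present in the series",
         call. = FALSE)
  }
  colMeans(flux[sel, , drop = FALSE])
}

#' Refugia vs non-refugia flux comparison with a spatial block bootstrap
#'
#' Difference of group means (refugia minus non-refugia) of a per-cell
#' field, with uncertainty from a spatial block bootstrap: the grid is
#' tiled into `block_size` x `block_size` cell blocks, blocks are
#' resampled with replacement, and the group difference is recomputed on
#' each resample. Resampling contiguous blocks rather than cells keeps
#' the spatial autocorrelation of the field in the standard error.
#'
#' @param flux Per-cell values (e.g. from [summer_flux_mean()]).
#' @param mask A `refugia_mask` on the same cells.
#' @param grid The `reef_grid` the cells live on (for block geometry).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param block_size Block edge length in cells (default 5).
#' @param seed Seed for the resampling (default 1).
#' @return A list: `difference` (refugia - non-refugia mean), `se`,
#'   `p_value` (two-sided normal approximation), `n_boot_effective`
#'   (resamples where both groups were represented), and the group means.
#' @export
compare_groups <- function(flux, mask, grid, n_boot = 2000L,
                           block_size = 5L, seed = 1L) {
  stopifnot(inherits(mask, "refugia_mask"), inherits(grid, "reef_grid"))
  flux <- as.numeric(flux)
  stopifnot(length(flux) == length(mask$is_refugium),
            length(flux) == n_cells(grid))
  ref <- mask$is_refugium
  if (!any(ref) || all(ref)) {
    stop("both refugia and non-refugia groups must be non-empty",
         call. = FALSE)
  }
  diff_hat <- mean(flux[ref]) - mean(flux[!ref])
  block_id <- paste((grid$cells$row - 1L) %/% block_size,
                    (grid$cells$col - 1L) %/% block_size)
  blocks <- split(seq_along(flux), block_id)
  nb <- length(blocks)
  boot <- with_seed(derive_seed(seed, 606L), {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(blocks[sample.int(nb, nb, replace = TRUE)],
                    use.names = FALSE)
      r <- ref[idx]
      if (!any(r) || all(r)) return(NA_real_)
      mean(flux[idx][r]) - mean(flux[idx][!r])
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  se <- stats::sd(boot)
  p <- if (!is.finite(se) || se == 0) {
    if (diff_hat == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(diff_hat / se))
  }
  list(difference = diff_hat, se = se, p_value = p,
       n_boot_effective = length(boot),
       mean_refugia = mean(flux[ref]), mean_non_refugia = mean(flux[!ref]))
}
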