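# Refugia-loss trajectories: the non-refugia minus refugia DHW difference
# per year, mapped onto global warming level, summarised by a quadratic
# fit whose zero crossing estimates the warming level at which refugia
# stop being relatively cool.

#' Non-refugia minus refugia DHW difference per year
#'
#' Aggregates annual-maximum DHW separately over non-refugia and refugia
#' cells (spatial median by default, matching the domain-median
#' convention used for stress trajectories) and returns their per-year
#' difference. Positive values mean refugia are still relatively cool.
#'
#' @param am An `annual_max`.
#' @param mask A `refugia_mask` on the same cells.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return Data frame with `year` and `diff` (degC-weeks).
#' @export
dhw_difference <- function(am, mask, aggregate = c("median", "mean")) {
  stopifnot(inherits(am, "annual_max"), inherits(mask, "refugia_mask"))
  aggregate <- match.arg(aggregate)
  if (ncol(am$annual_max) != length(mask$is_refugium)) {
    stop("grid mismatch between annual maxima and mask", call. = FALSE)
  }
  ref <- mask$is_refugium
  if (!any(ref) || all(ref)) {
    stop("both refugia and non-refugia groups must be non-empty",
         call. = FALSE)
  }
  agg <- if (aggregate == "median") stats::median else mean
  d <- apply(am$annual_max, 1, function(v) agg(v[!ref]) - agg(v[ref]))
  data.frame(year = am$years, diff = unname(d))
}

#' Centred rolling mean
#'
#' Centred moving average with an odd window; ends where the window is
#' incomplete are `NA`.
#'
#' @param x Numeric series.
#' @param window Odd window length, at most `length(x)` (default 11).
#' @return Numeric vector of the same length.
#' @export
rolling_mean <- function(x, window = 11L) {
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (window > length(x)) {
    stop("`window` longer than the series", call. = FALSE)
  }
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
}

#' Global warming anomaly relative to pre-industrial
#'
#' Annual global-mean temperature minus its 1860-1880 mean.
#'
#' @param tas A `global_tas` data frame (columns `year`, `tas`).
#' @param baseline Baseline years (default 1860:1880, inclusive).
#' @return Data frame with `year` and `anomaly` (degC).
#' @export
warming_anomaly <- function(tas, baseline = 1860:1880) {
  stopifnot(all(c("year", "tas") %in% names(tas)))
  missing <- setdiff(baseline, tas$year)
  if (length(missing)) {
    stop("baseline years missing from tas series: ",
         paste(range(missing), collapse = "-"), call. = FALSE)
  }
  ref <- mean(tas$tas[tas$year %in% baseline])
  data.frame(year = tas$year, anomaly = tas$tas - ref)
}

#' Quadratic fit of the DHW difference against warming level
#'
#' Ordinary least-squares second-degree polynomial of the (unsmoothed)
#' non-refugia minus refugia DHW difference on global warming anomaly,
#' pooling model-years across an ensemble. The reported `crossing` is the
#' smallest real root of the fitted quadratic that is positive, inside
#' the observed warming range, and at which the fitted curve is
#' decreasing: the warming level at which refugia stop holding a DHW
#' advantage.
#'
#' @param pairs Data frame with columns `warming` (degC anomaly) and
#'   `diff` (degC-weeks), one row per model-year; at least 6 rows.
#' @return A `quadratic_fit`: `coefficients` (a0, a1, a2), their
#'   `standard_errors`, `crossing` (degC, `NA` if no admissible root),
#'   `warming_range`, and the underlying `lm` fit.
#' @export
fit_diff_vs_warming <- function(pairs) {
  stopifnot(all(c("warming", "diff") %in% names(pairs)))
  pairs <- pairs[is.finite(pairs$warming) & is.finite(pairs$diff), ]
  if (nrow(pairs) < 6L) stop("need at least 6 (warming, diff) pairs",
                             call. = FALSE)
  fit <- stats::lm(diff ~ warming + I(warming^2), data = pairs)
  if (fit$rank < 3L) stop("rank-deficient design: warming values are too few",
                          call. = FALSE)
  cf <- stats::setNames(stats::coef(fit), c("a0", "a1", "a2"))
  se <- stats::setNames(sqrt(diag(stats::vcov(fit))), c("a0", "a1", "a2"))
  rng <- range(pairs$warming)
  roots <- if (abs(cf["a2"]) < 1e-12) {
    if (abs(cf["a1"]) < 1e-12) numeric(0) else -cf["a0"] / cf["a1"]
  } else {
    disc <- cf["a1"]^2 - 4 * cf["a2"] * cf["a0"]
    if (disc < 0) numeric(0) else {
      (-cf["a1"] + c(-1, 1) * sqrt(disc)) / (2 * cf["a2"])
    }
  }
  roots <- sort(roots[roots > 0 & roots >= rng[1] & roots <= rng[2]])
  # the refugia-loss point is where the fitted curve *descends* through
  # zero; an ascending root (possible at the low end of the warming range
  # when the early-era difference is near zero) is not a loss of refugia
  falling <- roots[cf["a1"] + 2 * cf["a2"] * roots < 0]
  crossing <- if (length(falling)) falling[1] else
    if (length(roots)) roots[1] else NA_real_
  structure(
    list(coefficients = cf, standard_errors = se,
         crossing = unname(crossing),
         warming_range = rng, fit = fit, n = nrow(pairs)),
    class = "quadratic_fit"
  )
}

#' Predict the fitted difference curve with a standard-error band
#'
#' @param object A `quadratic_fit`.
#' @param warming Warming levels at which to evaluate the curve.
#' @param ... Unused.
#' @return Data frame with `warming`, `fit` and `se`.
#' @export
predict.quadratic_fit <- function(object, warming, ...) {
  p <- stats::predict(object$fit, newdata = data.frame(warming = warming),
                      se.fit = TRUE)
  data.frame(warming = warming, fit = unname(p$fit), se = unname(p$se.fit))
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf(
    "<quadratic_fit> diff = %.3f + %.3f W + %.3f W^2 (n = %d); crossing %s\n",
    x$coefficients["a0"], x$coefficients["a1"], x$coefficients["a2"], x$n,
    if (is.na(x$crossing)) "none in range" else
      sprintf("at %.2f degC warming", x$crossing)
  ))
  invisible(x)
}

#' Relative warming slope of refugia cells
#'
#' Subtracts the per-year baseline median (non-refugia cells by default,
#' or the whole grid) from each refugia cell's annual-maximum DHW, then
#' fits a least-squares line against year over the fit period. Positive
#' slopes mean the cell is warming faster than its baseline — the
#' refugium is eroding.
#'
#' @param am An `annual_max` (typically from the highest-forcing
#'   scenario).
#' @param mask A `refugia_mask`.
#' @param baseline `"non_refugia"` (default) or `"grid"` median.
#' @param period Fit years (default 2014:2100).
#' @return A `slope_field`: `slope` (degC-weeks/year) per refugia cell,
#'   the refugia `cell` indices, `baseline` and `period`.
#' @export
relative_warming_slope <- function(am, mask,
                                   baseline = c("non_refugia", "grid"),
                                   period = 2014:2100) {
  stopifnot(inherits(am, "annual_max"), inherits(mask, "refugia_mask"))
  baseline <- match.arg(baseline)
  missing <- setdiff(period, am$years)
  if (length(missing)) {
    stop("annual maxima missing for year(s): ",
         paste(range(missing), collapse = "-"), call. = FALSE)
  }
  if (length(period) < 3L) stop("need at least 3 years", call. = FALSE)
  rows <- match(period, am$years)
  sub <- am$annual_max[rows, , drop = FALSE]
  base_cells <- if (baseline == "non_refugia") !mask$is_refugium else
    rep(TRUE, ncol(sub))
  base <- apply(sub[, base_cells, drop = FALSE], 1, stats::median)
  rel <- sub[, mask$is_refugium, drop = FALSE] - base
  x <- as.numeric(period) - mean(period)
  slope <- as.numeric(crossprod(x, rel)) / sum(x^2)
  structure(
    list(slope = slope, cell = which(mask$is_refugium),
         baseline = baseline, period = range(period)),
    class = "slope_field"
  )
}

#' Detect bleaching-condition years
#'
#' Years whose domain-median annual-maximum DHW reaches at least
#' `threshold` (default 2 degC-weeks, inclusive).
#'
#' @param gm Named per-year vector from [grid_median()] (or
#'   [ensemble_median()]).
#' @param threshold DHW threshold, degC-weeks (default 2).
#' @return Integer vector of years.
#' @export
detect_bleaching_years <- function(gm, threshold = 2) {
  as.integer(names(gm)[gm >= threshold])
}

#' Percentage change of an atmospheric field between bleaching eras
#'
#' Per-cell percentage change of the December-March mean of a daily
#' field, from the bleaching-condition years of a present window to those
#' of a future window:
#' `100 * (future mean - present mean) / present mean`.
#'
#' @param field Daily field, days x cells matrix (e.g. wind speed or
#'   shortwave radiation).
#' @param dates `Date` vector matching the rows.
#' @param bleaching_years Austral years with bleaching conditions, e.g.
#'   from [detect_bleaching_years()].
#' @param present Present-day window (default 1999:2019).
#' @param future Future window (default 2050:2100).
#' @param months Summer months (default December-March).
#' @return Numeric vector: percentage change per cell.
#' @export
atmos_change <- function(field, dates, bleaching_years,
                         present = 1999:2019, future = 2050:2100,
                         months = c(12L, 1L, 2L, 3L)) {
  stopifnot(is.matrix(field), length(dates) == nrow(field))
  p_years <- intersect(bleaching_years, present)
  f_years <- intersect(bleaching_years, future)
  if (!length(p_years) || !length(f_years)) {
    bad <- c(if (!length(p_years)) "present", if (!length(f_years)) "future")
    stop("no bleaching years in the ", paste(bad, collapse = " and "),
         " window", call. = FALSE)
  }
  pres <- summer_flux_mean(field, dates, years = p_years, months = months)
  fut <- summer_flux_mean(field, dates, years = f_years, months = months)
  100 * (fut - pres) / pres
}
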