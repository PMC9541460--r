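# HotSpot / degree-heating-week (DHW) stack. DHW accumulates qualifying
# warm anomalies (HotSpot >= 1 degC, the level at which coral thermal
# stress is conventionally taken to begin) over an 84-day running window,
# divided by 7 to convert degC-days to degC-weeks.

#' Daily warm SST anomalies (HotSpots)
#'
#' `max(SST - MMM, 0)` per day and cell: the instantaneous warm anomaly
#' above the bleaching-relevant climatological baseline.
#'
#' @param sst A `daily_sst`.
#' @param mmm An `mmm_field` with its `mmm` slot filled.
#' @return A `hotspot_series`: non-negative `hotspot` matrix
#'   (days x cells) plus `dates`.
#' @export
hotspot <- function(sst, mmm) {
  stopifnot(inherits(sst, "daily_sst"), inherits(mmm, "mmm_field"))
  if (is.null(mmm$mmm)) stop("`mmm` has no MMM values; run compute_mmm()",
                             call. = FALSE)
  if (ncol(sst$sst) != length(mmm$mmm)) {
    stop("grid mismatch: SST has ", ncol(sst$sst), " cells but MMM has ",
         length(mmm$mmm), call. = FALSE)
  }
  structure(
    list(hotspot = pmax(sweep(sst$sst, 2, mmm$mmm), 0), dates = sst$dates),
    class = "hotspot_series"
  )
}

#' Degree heating weeks
#'
#' Running 84-day accumulation of qualifying HotSpots, in degC-weeks:
#' `dhw(t) = sum over the 84 days ending at t of hotspot * [hotspot >=
#' hotspot_floor] / weekly_divisor`. The first `window_days - 1` days are
#' flagged missing — an incomplete window is not a valid accumulation,
#' not a zero one.
#'
#' @param hs A `hotspot_series` (daily, gap-free).
#' @param window_days Accumulation window, days (default 84, ~3 months).
#' @param hotspot_floor Minimum HotSpot that accumulates, degC
#'   (default 1); smaller anomalies contribute nothing.
#' @param weekly_divisor Days-to-weeks conversion (default 7). Set to 1
#'   for a literal degC-day accumulation.
#' @return A `dhw_series`: `dhw` matrix (days x cells, degC-weeks, first
#'   `window_days - 1` rows `NA`), `dates`, and the three parameters.
#' @export
dhw <- function(hs, window_days = 84L, hotspot_floor = 1,
                weekly_divisor = 7) {
  stopifnot(inherits(hs, "hotspot_series"))
  stopifnot_daily(hs$dates)
  n <- nrow(hs$hotspot)
  if (n < window_days) {
    stop("series shorter than the ", window_days, "-day window", call. = FALSE)
  }
  q <- hs$hotspot * (hs$hotspot >= hotspot_floor)
  cs <- rbind(0, apply(q, 2, cumsum))
  vals <- (cs[(window_days + 1L):(n + 1L), , drop = FALSE] -
             cs[1:(n - window_days + 1L), , drop = FALSE]) / weekly_divisor
  out <- matrix(NA_real_, n, ncol(q))
  out[window_days:n, ] <- vals
  structure(
    list(dhw = out, dates = hs$dates, window_days = window_days,
         hotspot_floor = hotspot_floor, weekly_divisor = weekly_divisor),
    class = "dhw_series"
  )
}

#' Annual maximum DHW by austral year
#'
#' Per-cell maximum DHW within each 1 August - 31 July span, labelled by
#' the span's ending calendar year so the austral summer sits in the
#' middle of the analysis year and is never split (nor double-counted)
#' across years. Spans not fully covered by valid (post-warm-up) data are
#' dropped with a warning.
#'
#' @param d A `dhw_series`.
#' @param convention `"austral"` (default) or `"calendar"`.
#' @return An `annual_max` object: `annual_max` matrix (years x cells)
#'   and the integer `years` labels.
#' @export
annual_max_dhw <- function(d, convention = c("austral", "calendar")) {
  stopifnot(inherits(d, "dhw_series"))
  convention <- match.arg(convention)
  valid <- !is.na(d$dhw[, 1])
  dates <- d$dates
  first_valid <- dates[which(valid)[1]]
  last <- dates[length(dates)]
  if (convention == "austral") {
    yr <- austral_year(dates)
    span_start <- function(y) as.Date(paste0(y - 1L, "-08-01"))
    span_end <- function(y) as.Date(paste0(y, "-07-31"))
  } else {
    yr <- as.integer(format(dates, "%Y"))
    span_start <- function(y) as.Date(paste0(y, "-01-01"))
    span_end <- function(y) as.Date(paste0(y, "-12-31"))
  }
  candidates <- sort(unique(yr))
  complete <- vapply(candidates, function(y) {
    span_start(y) >= first_valid && span_end(y) <= last
  }, logical(1))
  if (!all(complete)) {
    warning("dropping partial ", convention, " year(s): ",
            paste(candidates[!complete], collapse = ", "), call. = FALSE)
  }
  years <- candidates[complete]
  if (!length(years)) stop("no complete ", convention, " years", call. = FALSE)
  am <- matrix(NA_real_, length(years), ncol(d$dhw),
               dimnames = list(year = years, cell = NULL))
  for (i in seq_along(years)) {
    sel <- yr == years[i] & dates >= span_start(years[i]) &
      dates <= span_end(years[i])
    am[i, ] <- apply(d$dhw[sel, , drop = FALSE], 2, max)
  }
  structure(list(annual_max = am, years = years, convention = convention),
            class = "annual_max")
}

#' Spatial median of annual maxima
#'
#' The per-year median of annual-maximum DHW across the shelf cells of
#' one model: the domain-scale stress trajectory.
#'
#' @param am An `annual_max`.
#' @return Named numeric vector (one value per year).
#' @export
grid_median <- function(am) {
  stopifnot(inherits(am, "annual_max"))
  if (ncol(am$annual_max) < 1L) stop("empty spatial mask", call. = FALSE)
  stats::setNames(apply(am$annual_max, 1, stats::median), am$years)
}

#' Ensemble aggregate of per-model median trajectories
#'
#' Combines per-model spatial-median series into one per-scenario series.
#' The per-model medians are averaged across models by default; a
#' median-of-medians variant is available since either reading of
#' "averaged ... resulting in an ensemble median" is defensible.
#'
#' @param medians A list of named per-year vectors as returned by
#'   [grid_median()], one per model.
#' @param fun `"mean"` (default) or `"median"` across models.
#' @return Named numeric vector over the years common to all models.
#' @export
ensemble_median <- function(medians, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  stopifnot(length(medians) >= 1L)
  years <- Reduce(intersect, lapply(medians, names))
  if (!length(years)) stop("models share no years", call. = FALSE)
  m <- vapply(medians, function(v) v[years], numeric(length(years)))
  m <- matrix(m, nrow = length(years))
  agg <- if (fun == "mean") rowMeans(m) else apply(m, 1, stats::median)
  stats::setNames(agg, years)
}
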