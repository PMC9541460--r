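# Percentile-based refugia classification: cells in the lowest 20% of
# climatological mean annual-maximum DHW over 1999-2019 are flagged as
# thermal-exposure refugia; everything else on the shelf is non-refugia.

#' Climatological mean annual-maximum DHW
#'
#' Per-cell arithmetic mean of the annual maxima over a classification
#' period (default austral years 1999-2019).
#'
#' @param am An `annual_max`.
#' @param period Years to average over (default 1999:2019).
#' @return Numeric vector, one mean per cell.
#' @export
climatological_mean_dhw <- function(am, period = 1999:2019) {
  stopifnot(inherits(am, "annual_max"))
  missing <- setdiff(period, am$years)
  if (length(missing)) {
    stop("annual maxima missing for year(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  colMeans(am$annual_max[am$years %in% period, , drop = FALSE])
}

#' Classify thermal-stress refugia
#'
#' Flags the cells whose climatological mean DHW lies at or below the
#' `percentile`-th quantile of all valid cells (linear interpolation
#' between order statistics, the common scientific-software default).
#' Ties at the threshold are included.
#'
#' @param meanfield Per-cell climatological mean DHW, e.g. from
#'   [climatological_mean_dhw()].
#' @param percentile Fraction of cells targeted (default 0.2).
#' @param period Classification period, recorded for provenance.
#' @param quantile_type Quantile definition passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return A `refugia_mask`: logical `is_refugium` per cell,
#'   `threshold_value` (degC-weeks), `percentile`, `period`.
#' @export
classify_refugia <- function(meanfield, percentile = 0.2,
                             period = c(1999L, 2019L), quantile_type = 7) {
  x <- as.numeric(meanfield)
  if (sum(is.finite(x)) < 5L) {
    stop("need at least 5 valid cells to classify refugia", call. = FALSE)
  }
  thr <- unname(stats::quantile(x, percentile, type = quantile_type,
                                na.rm = TRUE))
  if (diff(range(x, na.rm = TRUE)) < .Machine$double.eps) {
    warning("all cells share one mean DHW value; every cell is flagged",
            call. = FALSE)
  }
  structure(
    list(is_refugium = x <= thr, threshold_value = thr,
         percentile = percentile, period = period),
    class = "refugia_mask"
  )
}

#' @export
print.refugia_mask <- function(x, ...) {
  cat(sprintf(
    "<refugia_mask> %d of %d cells at/below the %.0fth percentile (%.3f degC-weeks)\n",
    sum(x$is_refugium), length(x$is_refugium), 100 * x$percentile,
    x$threshold_value
  ))
  invisible(x)
}

#' Multi-model refugia agreement map
#'
#' Per-cell count of models whose refugia masks flag the cell; with five
#' models the count runs 0 (no agreement) to 5 (all models agree).
#'
#' @param masks List of `refugia_mask` objects on the same cells.
#' @return An `agreement_map` with integer `n_agree` per cell and
#'   `n_models`.
#' @export
model_agreement <- function(masks) {
  stopifnot(length(masks) >= 1L)
  lens <- vapply(masks, function(m) length(m$is_refugium), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("grid mismatch: masks have differing cell counts", call. = FALSE)
  }
  n_agree <- Reduce(`+`, lapply(masks, function(m) as.integer(m$is_refugium)))
  structure(list(n_agree = n_agree, n_models = length(masks)),
            class = "agreement_map")
}

#' Agreement with a reference refugia mask
#'
#' Cells flagged by a reference classification (e.g. a reanalysis-driven
#' run) where at least `min_models` ensemble members also flag refugia.
#'
#' @param masks List of model `refugia_mask`s.
#' @param reference The reference `refugia_mask`.
#' @param min_models Minimum agreeing models (default 2).
#' @return Logical vector per cell.
#' @export
reference_agreement <- function(masks, reference, min_models = 2L) {
  agree <- model_agreement(masks)
  if (length(reference$is_refugium) != length(agree$n_agree)) {
    stop("grid mismatch between reference and model masks", call. = FALSE)
  }
  reference$is_refugium & agree$n_agree >= min_models
}

#' Per-year persistence of a refugia classification
#'
#' For each year, recomputes the 20th-percentile threshold over that
#' year's annual-maximum DHW across all cells, and reports the fraction
#' of the classified refugia cells still at or below it. Rank-based, so
#' invariant to spatially uniform warming within a year; refugia are
#' "lost" only when other cells become relatively cooler.
#'
#' @param am An `annual_max` (any span of years).
#' @param mask A `refugia_mask` from the same grid.
#' @param percentile Percentile re-evaluated each year (defaults to the
#'   mask's own).
#' @param quantile_type Quantile definition (default 7).
#' @return Data frame with `year` and `fraction_below`.
#' @export
persistence <- function(am, mask, percentile = mask$percentile,
                        quantile_type = 7) {
  stopifnot(inherits(am, "annual_max"), inherits(mask, "refugia_mask"))
  if (ncol(am$annual_max) != length(mask$is_refugium)) {
    stop("grid mismatch between annual maxima and mask", call. = FALSE)
  }
  if (!any(mask$is_refugium)) stop("empty refugia mask", call. = FALSE)
  frac <- apply(am$annual_max, 1, function(v) {
    thr <- stats::quantile(v, percentile, type = quantile_type, na.rm = TRUE)
    mean(v[mask$is_refugium] <= thr)
  })
  data.frame(year = am$years, fraction_below = unname(frac))
}
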