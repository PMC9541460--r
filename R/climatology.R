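# Maximum-monthly-mean (MMM) climatology, Coral Reef Watch style: monthly
# means over a 28-year base period, recentred per month by least-squares
# regression to the fixed centre year 1988.2857. The odd centre year is a
# convention inherited from the satellite climatology, which was adjusted
# to match an original 7-year record with Mt Pinatubo-affected years
# removed; here it is simply the abscissa at which the monthly regression
# lines are evaluated, with no special-casing.

#' Monthly mean SST per climatology year
#'
#' Averages daily SST within each calendar month of each requested year,
#' giving 12 monthly means per year per cell. All days in a month weigh
#' equally (leap days included).
#'
#' @param sst A `daily_sst` object.
#' @param years Climatology years (default 1985:2012, the 28-year base
#'   period).
#' @return An object of class `monthly_means`: `values` array
#'   (12 months x years x cells), `counts` matrix of days averaged
#'   (12 x years), and `years`.
#' @export
monthly_means_by_year <- function(sst, years = 1985:2012) {
  stopifnot(inherits(sst, "daily_sst"))
  y <- as.integer(format(sst$dates, "%Y"))
  m <- as.integer(format(sst$dates, "%m"))
  keep <- y %in% years
  got <- unique(paste(y[keep], sprintf("%02d", m[keep])))
  want <- as.vector(outer(sprintf("%02d", 1:12), years,
                          function(mm, yy) paste(yy, mm)))
  missing <- setdiff(want, got)
  if (length(missing)) {
    stop("no daily values for month(s): ",
         paste(utils::head(sort(missing), 6), collapse = ", "),
         if (length(missing) > 6) " ...", call. = FALSE)
  }
  grp <- factor(paste(y[keep], sprintf("%02d", m[keep])), levels = sort(want))
  counts <- as.integer(table(grp))
  sums <- rowsum(sst$sst[keep, , drop = FALSE], grp)
  means <- sums / counts
  # rows of `means` are year-major (all months of the first year, then the
  # next); reshape to (month, year, cell)
  nyr <- length(years)
  nc <- ncol(means)
  values <- array(NA_real_, c(12L, nyr, nc),
                  dimnames = list(month = 1:12, year = years, cell = NULL))
  for (j in seq_len(nyr)) {
    values[, j, ] <- means[(j - 1L) * 12L + 1:12, ]
  }
  structure(
    list(values = values,
         counts = matrix(counts, 12L, nyr,
                         dimnames = list(month = 1:12, year = years)),
         years = years),
    class = "monthly_means"
  )
}

#' Recentre a monthly climatology to a fixed centre year
#'
#' For each cell and month, fits an ordinary least-squares line of the
#' yearly monthly means against calendar year and evaluates it at
#' `centre_year`, removing the warming trend across the base period from
#' the climatology. The regression abscissa is the integer calendar year.
#'
#' @param mm A `monthly_means` object.
#' @param centre_year Year at which the fitted lines are evaluated
#'   (default 1988.2857).
#' @return An `mmm_field` with the `climatology` matrix (12 x cells)
#'   filled in; use [compute_mmm()] for the per-cell maximum.
#' @export
recentre_climatology <- function(mm, centre_year = 1988.2857) {
  stopifnot(inherits(mm, "monthly_means"))
  x <- as.numeric(mm$years)
  if (length(unique(x)) < 2L) {
    stop("degenerate fit: need at least 2 distinct climatology years",
         call. = FALSE)
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  nc <- dim(mm$values)[3]
  clim <- matrix(NA_real_, 12L, nc)
  for (mo in 1:12) {
    y <- matrix(mm$values[mo, , ], length(x), nc)   # years x cells
    slope <- as.numeric(crossprod(xc, y)) / sxx
    clim[mo, ] <- colMeans(y) + slope * (centre_year - mean(x))
  }
  structure(
    list(climatology = clim, mmm = NULL, centre_year = centre_year),
    class = "mmm_field"
  )
}

#' Maximum monthly mean (MMM)
#'
#' The warmest of the 12 recentred monthly climatological means per cell:
#' the baseline against which warm anomalies (HotSpots) are measured.
#'
#' @param clim An `mmm_field` from [recentre_climatology()].
#' @return The same `mmm_field` with the per-cell `mmm` vector filled in.
#' @export
compute_mmm <- function(clim) {
  stopifnot(inherits(clim, "mmm_field"))
  if (anyNA(clim$climatology)) {
    stop("climatology has missing monthly values", call. = FALSE)
  }
  clim$mmm <- apply(clim$climatology, 2, max)
  clim
}

#' Full MMM climatology from daily SST
#'
#' Convenience wrapper: [monthly_means_by_year()], then
#' [recentre_climatology()], then [compute_mmm()].
#'
#' @inheritParams monthly_means_by_year
#' @inheritParams recentre_climatology
#' @return A complete `mmm_field`.
#' @export
mmm_climatology <- function(sst, years = 1985:2012, centre_year = 1988.2857) {
  compute_mmm(recentre_climatology(monthly_means_by_year(sst, years),
                                   centre_year))
}

#' @export
print.mmm_field <- function(x, ...) {
  cat(sprintf("<mmm_field> %d cells, centre year %.4f%s\n",
              ncol(x$climatology), x$centre_year,
              if (is.null(x$mmm)) " (mmm not yet computed)" else
                sprintf(", MMM %.2f-%.2f degC", min(x$mmm), max(x$mmm))))
  invisible(x)
}
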