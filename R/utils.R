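# Internal helpers shared across modules: seeded RNG scoping, calendar
# arithmetic, and smooth random fields used by the generators.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG to a reproducible state for the duration of `expr` and
#' restores the caller's state afterwards, so library functions never
#' perturb a user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific seed from a base seed; keeps results < 2^31 and
# decorrelates the substreams used by different generator stages.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 2654435761 + as.double(stream) * 40503) %% 2147483647
  as.integer(s)
}

#' Decimal year of a date
#'
#' Gregorian, leap-aware fractional year of each date.
#'
#' @param dates A `Date` vector.
#' @return Numeric vector of fractional years.
#' @export
decimal_year <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  start <- as.Date(paste0(y, "-01-01"))
  end <- as.Date(paste0(y + 1L, "-01-01"))
  y + as.numeric(dates - start) / as.numeric(end - start)
}

# Austral-year label: the 12-month span Aug 1 (y-1) .. Jul 31 (y) is
# labelled by its ending calendar year y, so the southern-hemisphere
# summer (DJFM) sits in the middle of the analysis year.
austral_year <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  y + as.integer(m >= 8L)
}

#' Daily date sequence spanning whole calendar years
#'
#' @param years Integer years; the sequence runs 1 January of the first
#'   to 31 December of the last.
#' @return A `Date` vector.
#' @export
daily_dates <- function(years) {
  seq(as.Date(paste0(min(years), "-01-01")),
      as.Date(paste0(max(years), "-12-31")), by = "day")
}

stopifnot_daily <- function(dates) {
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L)) {
    stop("series must be daily and gap-free", call. = FALSE)
  }
  invisible(dates)
}

# Smooth pseudo-random surface on an nlat x nlon grid: a small sum of
# random low-wavenumber cosines, rescaled to [0, 1]. Correlation length is
# a few cells by construction, which is all the generators need.
smooth_field <- function(nlat, nlon, n_modes = 6L, wavelength = 12) {
  x <- matrix(rep(seq_len(nlon), each = nlat), nlat, nlon)
  y <- matrix(rep(seq_len(nlat), nlon), nlat, nlon)
  f <- matrix(0, nlat, nlon)
  for (k in seq_len(n_modes)) {
    kx <- stats::rnorm(1, 0, 2 * pi / wavelength)
    ky <- stats::rnorm(1, 0, 2 * pi / wavelength)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::rnorm(1, 0, 1) * cos(kx * x + ky * y + ph)
  }
  rng <- range(f)
  if (diff(rng) < .Machine$double.eps) {
    return(matrix(0.5, nlat, nlon))
  }
  (f - rng[1]) / diff(rng)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
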