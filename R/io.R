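# Plain-text serialisation of the pipeline's gridded and series data.
# Files are CSV with a small '#'-prefixed metadata header (key: value),
# so every artefact is diffable and self-describing.

write_meta_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_meta_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    k <- sub(":.*$", "", kv)
    meta[[trimws(k)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"))
  attr(df, "meta") <- meta
  df
}

#' Write / read a daily SST field as CSV
#'
#' Wide CSV: one `date` column plus one column per shelf cell, with
#' provenance (model, scenario, seed, calendar) in a `#` header.
#' On read, a `noleap` calendar is accepted: 365-day years are expanded
#' to the Gregorian calendar by linearly interpolating the missing
#' 29 February, so downstream daily-window operations see a gap-free
#' series.
#'
#' @param sst A `daily_sst`.
#' @param path File path.
#' @return `write_sst_csv` returns `path` invisibly; `read_sst_csv`
#'   returns a `daily_sst`.
#' @export
write_sst_csv <- function(sst, path) {
  stopifnot(inherits(sst, "daily_sst"))
  df <- data.frame(date = format(sst$dates), sst$sst)
  names(df) <- c("date", paste0("cell", seq_len(ncol(sst$sst))))
  write_meta_csv(df, path, list(
    model_id = sst$model_id, scenario_id = sst$scenario_id,
    seed = sst$seed, calendar = "gregorian", units = "degC"
  ))
}

#' @rdname write_sst_csv
#' @export
read_sst_csv <- function(path) {
  df <- read_meta_csv(path)
  meta <- attr(df, "meta")
  calendar <- meta$calendar %||% "gregorian"
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (identical(calendar, "noleap")) {
    parts <- do.call(rbind, strsplit(df$date, "-"))
    dates <- as.Date(paste0(parts[, 1], "-", parts[, 2], "-", parts[, 3]))
    full <- seq(min(dates), max(dates), by = "day")
    out <- matrix(NA_real_, length(full), ncol(mat))
    out[match(dates, full), ] <- mat
    feb29 <- which(format(full, "%m-%d") == "02-29")
    for (i in feb29) {
      out[i, ] <- colMeans(out[c(i - 1L, i + 1L), , drop = FALSE])
    }
    mat <- out
    df_dates <- full
  } else {
    df_dates <- as.Date(df$date)
  }
  structure(
    list(sst = unname(mat), dates = df_dates,
         damping_strength = NULL,
         model_id = meta$model_id %||% NA_character_,
         scenario_id = meta$scenario_id %||% NA_character_,
         seed = as.integer(meta$seed %||% NA),
         grid_signature = NULL),
    class = "daily_sst"
  )
}

#' Write / read a global temperature series as a two-column table
#'
#' @param tas A `global_tas` data frame.
#' @param path File path.
#' @return `write_tas_csv` returns `path` invisibly; `read_tas_csv` a
#'   `global_tas`.
#' @export
write_tas_csv <- function(tas, path) {
  write_meta_csv(data.frame(year = tas$year, tas = tas$tas), path,
                 list(units = "degC", variable = "tas"))
}

#' @rdname write_tas_csv
#' @export
read_tas_csv <- function(path) {
  df <- read_meta_csv(path)
  structure(data.frame(year = as.integer(df$year), tas = as.numeric(df$tas)),
            class = c("global_tas", "data.frame"))
}

#' Write a reef grid as CSV
#'
#' One row per masked-in cell (row, col, lon, lat, depth).
#'
#' @param grid A `reef_grid`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  write_meta_csv(grid$cells, path, list(
    resolution_deg = grid$resolution, seed = grid$seed,
    nlat = length(grid$lat), nlon = length(grid$lon)
  ))
}
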