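#' Hourly air-temperature series
#'
#' Container for one winter of hourly air-temperature readings, the raw
#' input of the chill accumulation models. Timestamps must be strictly
#' increasing on an hourly grid; gaps (missing hours) are detected and
#' recorded in the `gaps` attribute, never silently filled. Temperatures
#' outside the plausible sensor range \eqn{[-30, 50]} degrees C are rejected.
#'
#' @param timestamp `POSIXct` vector (or strings coercible via
#'   [as.POSIXct()]) at hourly resolution, naive local clock time.
#' @param temp_c numeric vector of air temperatures in degrees C.
#' @param season_label free-text label for the winter, e.g. `"2012-2013"`.
#' @return An object of class `hourly_series`: a data frame with columns
#'   `timestamp` and `temp_c` and attributes `season_label` and `gaps`
#'   (a data frame listing each gap's position and length in hours).
#' @examples
#' ts <- seq(as.POSIXct("2012-12-01 00:00", tz = "UTC"), by = "hour",
#'           length.out = 48)
#' s <- hourly_series(ts, rep(5, 48), "toy")
#' daily_means(s)
#' @export
hourly_series <- function(timestamp, temp_c, season_label = "") {
  if (is.character(timestamp)) {
    timestamp <- as.POSIXct(timestamp, tz = "UTC")
  }
  if (!inherits(timestamp, "POSIXct")) {
    abort("timestamp must be POSIXct or parseable date-time strings",
          "budchill_input_error")
  }
  if (anyNA(timestamp)) {
    abort("unparseable or missing timestamps in series",
          "budchill_input_error")
  }
  if (length(timestamp) != length(temp_c)) {
    abort("timestamp and temp_c lengths differ", "budchill_input_error")
  }
  if (length(timestamp) == 0L) {
    abort("empty temperature series", "budchill_input_error")
  }
  temp_c <- as.numeric(temp_c)
  if (any(!is.finite(temp_c))) {
    abort("non-finite temperatures in series", "budchill_input_error")
  }
  if (any(temp_c < -30 | temp_c > 50)) {
    bad <- which(temp_c < -30 | temp_c > 50)[1L]
    abort(sprintf("temperature %.1f at %s outside [-30, 50] degC (sensor error)",
                  temp_c[bad], format(timestamp[bad])),
          "budchill_input_error")
  }
  dh <- as.numeric(diff(as.numeric(timestamp))) / 3600
  if (any(dh <= 0)) {
    i <- which(dh <= 0)[1L]
    abort(sprintf("timestamps not strictly increasing at %s (duplicated or out of order hour)",
                  format(timestamp[i + 1L])),
          "budchill_duplicate_error")
  }
  if (any(abs(dh - round(dh)) > 1e-6)) {
    i <- which(abs(dh - round(dh)) > 1e-6)[1L]
    abort(sprintf("non-hourly spacing between %s and %s",
                  format(timestamp[i]), format(timestamp[i + 1L])),
          "budchill_input_error")
  }
  gap_at <- which(round(dh) > 1)
  gaps <- data.frame(
    after = timestamp[gap_at],
    missing_hours = round(dh[gap_at]) - 1L
  )
  out <- data.frame(timestamp = timestamp, temp_c = temp_c)
  attr(out, "season_label") <- season_label
  attr(out, "gaps") <- gaps
  class(out) <- c("hourly_series", "data.frame")
  out
}

#' @export
print.hourly_series <- function(x, ...) {
  g <- attr(x, "gaps")
  cat(sprintf("Hourly temperature series '%s'\n", attr(x, "season_label")))
  cat(sprintf("  %d records, %s .. %s\n", nrow(x),
              format(x$timestamp[1L]), format(x$timestamp[nrow(x)])))
  cat(sprintf("  temp range %.1f .. %.1f degC, %d gap(s) (%d missing hours)\n",
              min(x$temp_c), max(x$temp_c), nrow(g),
              if (nrow(g)) sum(g$missing_hours) else 0L))
  invisible(x)
}

#' Gaps flagged in an hourly series
#'
#' @param series an [hourly_series()].
#' @return data frame with columns `after` (last timestamp before the gap)
#'   and `missing_hours`.
#' @export
series_gaps <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  attr(series, "gaps")
}

#' Daily mean temperatures
#'
#' Arithmetic mean of each calendar date's hourly readings. Dates with
#' fewer than 24 readings are kept but flagged incomplete, since their mean
#' rests on a partial day.
#'
#' @param series an [hourly_series()].
#' @return data frame with columns `date`, `mean_c`, `n_hours`, `complete`.
#' @export
daily_means <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  d <- as.Date(series$timestamp, tz = "UTC")
  agg <- aggregate(series$temp_c, by = list(date = d),
                   FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(
    date = agg$date,
    mean_c = agg$x[, 1L],
    n_hours = as.integer(agg$x[, 2L])
  )
  out$complete <- out$n_hours == 24L
  out[order(out$date), , drop = FALSE]
}

#' Detect the chill-accumulation start date
#'
#' Finds the first calendar date from which the daily mean temperature
#' stays strictly below `threshold_c` for `persistence_days` consecutive
#' dates, operationalizing a mean that has "steadily passed" below the
#' model's upper effective temperature. Returns midnight of that date.
#'
#' @param series an [hourly_series()].
#' @param threshold_c threshold in degrees C (7.2 for the chill-hour model,
#'   10 for the chill-unit model).
#' @param persistence_days number of consecutive qualifying dates required
#'   (default 3); higher values tolerate isolated warm spikes.
#' @return `POSIXct` midnight of the detected start date.
#' @export
detect_start_date <- function(series, threshold_c, persistence_days = 3) {
  stopifnot_scalar_number(threshold_c, "threshold_c")
  if (persistence_days < 1) {
    abort("persistence_days must be >= 1", "budchill_config_error")
  }
  dm <- daily_means(series)
  below <- dm$mean_c < threshold_c
  # require calendar-consecutive dates, not just consecutive rows
  n <- nrow(dm)
  k <- as.integer(persistence_days)
  if (n >= k) {
    for (i in seq_len(n - k + 1L)) {
      idx <- i:(i + k - 1L)
      if (all(below[idx]) &&
          all(diff(as.integer(dm$date[idx])) == 1L)) {
        return(as.POSIXct(paste(dm$date[i], "00:00:00"), tz = "UTC"))
      }
    }
  }
  abort(sprintf("no run of %d consecutive days with mean below %.1f degC",
                k, threshold_c),
        "budchill_not_found_error")
}

#' Read an hourly temperature table
#'
#' Reads a delimited text file with a header row into an
#' [hourly_series()]. The default layout has columns `timestamp`
#' (ISO 8601, hourly) and `temp_c`; other layouts are loadable by naming
#' their columns in `mapping`.
#'
#' @param path file path.
#' @param mapping named list mapping `timestamp` and `temp_c` to the
#'   column names used in the file.
#' @param sep field separator; `NULL` auto-detects comma vs tab.
#' @param season_label label passed through to the series.
#' @param timestamp_format optional [strptime()] format string; by default
#'   ISO 8601 variants are tried.
#' @return an [hourly_series()].
#' @export
read_temperature_table <- function(path,
                                   mapping = list(timestamp = "timestamp",
                                                  temp_c = "temp_c"),
                                   sep = NULL, season_label = "",
                                   timestamp_format = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "budchill_io_error")
  }
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("timestamp", "temp_c")) {
    nm <- mapping[[col]]
    if (is.null(nm) || !nm %in% names(tab)) {
      abort(sprintf("mapped column '%s' (%s) absent from %s",
                    nm %||% "<unset>", col, path),
            "budchill_io_error")
    }
  }
  raw_ts <- tab[[mapping$timestamp]]
  parse_ts <- function(v) {
    if (is.null(timestamp_format)) {
      as.POSIXct(v, tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                                "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
    } else {
      as.POSIXct(v, tz = "UTC", format = timestamp_format)
    }
  }
  ts <- tryCatch(parse_ts(raw_ts), error = function(e) NULL)
  if (is.null(ts) || anyNA(ts)) {
    ok <- vapply(raw_ts, function(x) {
      !is.na(tryCatch(parse_ts(x), error = function(e) NA))
    }, logical(1))
    bad <- which(!ok)[1L]
    abort(sprintf("unparseable timestamp '%s' at data line %d of %s",
                  raw_ts[bad], bad, path),
          "budchill_io_error")
  }
  hourly_series(ts, tab[[mapping$temp_c]], season_label = season_label)
}

#' Write an hourly temperature table
#'
#' Writes the two-column layout [read_temperature_table()] consumes, so
#' generated fixtures round-trip exactly.
#'
#' @param series an [hourly_series()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_temperature_table <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "hourly_series"))
  out <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S"),
    temp_c = series$temp_c
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
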