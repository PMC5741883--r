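#' Chill-hour (CH) weighting model
#'
#' Under the cumulative chill-hour model every hour whose temperature lies
#' inside the effective band counts as one chill hour; hours outside count
#' zero. The band endpoints (0 and 7.2 degrees C by default) are included.
#'
#' @param t_low lower effective temperature, degrees C.
#' @param t_high upper effective temperature, degrees C.
#' @param inclusive_bounds logical: are readings exactly at the endpoints
#'   credited? Default `TRUE`.
#' @return an object of class `c("chill_hours_model", "chill_model")`.
#' @examples
#' chill_weight(chill_hours(), c(-1, 0, 5, 7.2, 8))
#' @export
chill_hours <- function(t_low = 0, t_high = 7.2, inclusive_bounds = TRUE) {
  stopifnot_scalar_number(t_low, "t_low")
  stopifnot_scalar_number(t_high, "t_high")
  if (t_low >= t_high) abort("t_low must be < t_high", "budchill_config_error")
  structure(
    list(t_low = t_low, t_high = t_high,
         inclusive_bounds = isTRUE(inclusive_bounds), units = "CH"),
    class = c("chill_hours_model", "chill_model")
  )
}

#' Chill-unit (CU) weighting model
#'
#' A temperature-weighted chill model: one hour below `t_zero` earns a full
#' chill unit, one hour above `t_max` earns none, and between them the
#' weight declines linearly, `weight = slope * t + intercept` (default
#' `-0.0605 * t + 1`, so an hour at 2 degrees C earns 0.879 CU).
#'
#' @param slope per-degree slope of the linear segment (negative).
#' @param intercept weight at 0 degrees C (default 1).
#' @param t_zero temperature at and below which the weight is `intercept`
#'   capped at 1 (default 0 degrees C; below it the weight is 1).
#' @param t_max temperature above which the weight is 0 (default 10).
#' @return an object of class `c("chill_units_model", "chill_model")`.
#' @examples
#' chill_weight(chill_units(), c(-5, 0, 2, 10, 12))
#' @export
chill_units <- function(slope = -0.0605, intercept = 1, t_zero = 0,
                        t_max = 10) {
  stopifnot_scalar_number(slope, "slope")
  stopifnot_scalar_number(intercept, "intercept")
  stopifnot_scalar_number(t_zero, "t_zero")
  stopifnot_scalar_number(t_max, "t_max")
  if (t_zero >= t_max) abort("t_zero must be < t_max", "budchill_config_error")
  if (slope >= 0) abort("slope must be negative", "budchill_config_error")
  w0 <- slope * t_zero + intercept
  wm <- slope * t_max + intercept
  if (w0 > 1 + 1e-12 || wm < -1e-12) {
    abort("linear segment must keep weights inside [0, 1]",
          "budchill_config_error")
  }
  structure(
    list(slope = slope, intercept = intercept, t_zero = t_zero,
         t_max = t_max, units = "CU"),
    class = c("chill_units_model", "chill_model")
  )
}

#' @export
print.chill_model <- function(x, ...) {
  if (inherits(x, "chill_hours_model")) {
    cat(sprintf("Chill-hour model: weight 1 for t in %s%.1f, %.1f%s degC\n",
                if (x$inclusive_bounds) "[" else "(",
                x$t_low, x$t_high,
                if (x$inclusive_bounds) "]" else ")"))
  } else {
    cat(sprintf(
      "Chill-unit model: 1 below %.1f degC, %.4f*t + %.2f on [%.1f, %.1f], 0 above\n",
      x$t_zero, x$slope, x$intercept, x$t_zero, x$t_max))
  }
  invisible(x)
}

#' Per-hour chill weight of a temperature
#'
#' @param model a [chill_hours()] or [chill_units()] model.
#' @param temp_c numeric vector of temperatures, degrees C; must be finite.
#' @return numeric vector of weights in `[0, 1]` (0/1 for the CH model).
#' @export
chill_weight <- function(model, temp_c) UseMethod("chill_weight")

#' @export
chill_weight.chill_hours_model <- function(model, temp_c) {
  if (any(!is.finite(temp_c))) {
    abort("non-finite temperature passed to chill_weight",
          "budchill_input_error")
  }
  inside <- if (model$inclusive_bounds) {
    temp_c >= model$t_low & temp_c <= model$t_high
  } else {
    temp_c > model$t_low & temp_c < model$t_high
  }
  as.numeric(inside)
}

#' @export
chill_weight.chill_units_model <- function(model, temp_c) {
  if (any(!is.finite(temp_c))) {
    abort("non-finite temperature passed to chill_weight",
          "budchill_input_error")
  }
  w <- model$slope * temp_c + model$intercept
  w[temp_c < model$t_zero] <- 1
  w[temp_c > model$t_max] <- 0
  pmin(pmax(w, 0), 1)
}

#' Accumulate chill over a time window of an hourly series
#'
#' Sums per-hour chill weights over the records falling in the half-open
#' window `[start, end)`. The half-open convention makes accumulation
#' additive over adjacent windows and never double-counts a transfer
#' instant. Missing hours inside the window are an error by default
#' (silent gaps bias chill sums low); short gaps can instead be linearly
#' interpolated.
#'
#' @param series an [hourly_series()].
#' @param start,end window endpoints (`POSIXct` or parseable strings);
#'   `start < end` required, window must lie within the series span.
#' @param model a [chill_hours()] or [chill_units()] model.
#' @param interpolate_gaps if `TRUE`, gaps of at most `max_gap_hours`
#'   inside the window are filled by linear interpolation between the
#'   neighbouring readings before weighting.
#' @param max_gap_hours largest gap eligible for interpolation (default 3).
#' @return total chill (hours for CH, units for CU) with attributes
#'   `n_hours` (window length in hours) and `n_flagged` (hours filled by
#'   interpolation). Full precision; round only at the presentation layer
#'   (see [round_half_up()]).
#' @export
accumulate_chill <- function(series, start, end, model,
                             interpolate_gaps = FALSE, max_gap_hours = 3) {
  stopifnot(inherits(series, "hourly_series"), inherits(model, "chill_model"))
  start <- as_instant(start)
  end <- as_instant(end)
  if (!(start < end)) abort("start must precede end", "budchill_input_error")
  ts <- series$timestamp
  span_lo <- ts[1L]
  span_hi <- ts[length(ts)] + 3600  # last record covers [last, last + 1h)
  if (start < span_lo || end > span_hi) {
    abort(sprintf("window %s .. %s outside series span %s .. %s",
                  format(start), format(end), format(span_lo),
                  format(span_hi)),
          "budchill_range_error")
  }
  sel <- ts >= start & ts < end
  n_expected <- round(as.numeric(difftime(end, start, units = "hours")))
  got <- sum(sel)
  n_flagged <- 0L
  temps <- series$temp_c[sel]
  if (got < n_expected) {
    expected <- seq(ceiling_hour(start), by = 3600,
                    length.out = n_expected)
    missing <- expected[!expected %in% as.numeric(ts)]
    if (!interpolate_gaps ||
        longest_run(sort(missing)) > max_gap_hours) {
      abort(sprintf(
        "%d missing hour(s) inside window (first: %s); set interpolate_gaps = TRUE for gaps of <= %d h",
        length(missing),
        format(as.POSIXct(missing[1L], tz = "UTC", origin = "1970-01-01")),
        max_gap_hours),
        "budchill_gap_error")
    }
    filled <- stats::approx(as.numeric(ts), series$temp_c, xout = missing)$y
    if (anyNA(filled)) {
      abort("gap at series boundary cannot be interpolated",
            "budchill_gap_error")
    }
    temps <- c(temps, filled)
    n_flagged <- length(missing)
  }
  total <- sum(chill_weight(model, temps))
  structure(total, n_hours = n_expected, n_flagged = n_flagged)
}

# longest run of consecutive missing hours (inputs: sorted timestamps)
longest_run <- function(missing) {
  if (length(missing) == 0L) return(0L)
  r <- rle(c(TRUE, diff(as.numeric(missing)) == 3600))
  max(r$lengths[r$values])
}

ceiling_hour <- function(x) {
  s <- as.numeric(x)
  as.POSIXct(ceiling(s / 3600) * 3600, tz = "UTC", origin = "1970-01-01")
}

as_instant <- function(x) {
  if (is.character(x)) {
    x <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  }
  if (!inherits(x, "POSIXct") || anyNA(x)) {
    abort("window endpoints must be POSIXct or parseable date-times",
          "budchill_input_error")
  }
  x
}

#' Chill accumulated at a constant storage temperature
#'
#' Closed form for refrigerated storage: `hours * weight(t_const)`. Equals
#' [accumulate_chill()] on a constant synthetic series of the same length.
#' Seven days of storage at 2 degrees C earn `168 * 0.879 = 147.672` CU
#' (printed 147.67) or 168 CH.
#'
#' @param t_const storage temperature, degrees C.
#' @param hours number of storage hours, `>= 0`.
#' @param model a [chill_hours()] or [chill_units()] model.
#' @return total chill, full precision.
#' @export
constant_chill <- function(t_const, hours, model) {
  stopifnot_scalar_number(t_const, "t_const")
  stopifnot_scalar_number(hours, "hours")
  if (hours < 0) abort("hours must be >= 0", "budchill_input_error")
  stopifnot(inherits(model, "chill_model"))
  hours * chill_weight(model, t_const)
}

#' Tabulate chill accumulation over several windows
#'
#' Convenience wrapper producing the report layout written by
#' [write_accumulation_report()].
#'
#' @param series an [hourly_series()].
#' @param windows data frame with columns `start` and `end`.
#' @param model a chill model.
#' @param ... passed to [accumulate_chill()].
#' @return data frame with columns `window_start`, `window_end`, `model`,
#'   `total`, `n_hours`, `n_flagged`.
#' @export
accumulation_report <- function(series, windows, model, ...) {
  stopifnot(is.data.frame(windows), all(c("start", "end") %in% names(windows)))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    tot <- accumulate_chill(series, windows$start[i], windows$end[i],
                            model, ...)
    data.frame(
      window_start = format(as_instant(windows$start[i]), "%Y-%m-%dT%H:%M:%S"),
      window_end = format(as_instant(windows$end[i]), "%Y-%m-%dT%H:%M:%S"),
      model = model$units,
      total = as.numeric(tot),
      n_hours = attr(tot, "n_hours"),
      n_flagged = attr(tot, "n_flagged")
    )
  })
  do.call(rbind, rows)
}

#' Write an accumulation report
#'
#' Chill totals are printed to two decimals (half-up); all other columns
#' verbatim.
#'
#' @param report output of [accumulation_report()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_accumulation_report <- function(report, path, sep = ",") {
  report$total <- format_chill(report$total)
  utils::write.table(report, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
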