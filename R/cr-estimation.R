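#' Define a chilling treatment
#'
#' A treatment is one group of plants exposed to chill before forcing:
#' either `natural` (outdoors until transfer into the glasshouse, chill
#' accumulated from recorded hourly temperatures) or `artificial`
#' (refrigerated storage at a constant temperature, chill from the closed
#' form).
#'
#' @param id treatment label, e.g. `"Tre. 2-5"`.
#' @param mode `"natural"` or `"artificial"`.
#' @param chill_start start of the chilling exposure (storage entry for
#'   artificial treatments; for natural treatments usually the detected
#'   start date, see [detect_start_date()]).
#' @param chill_end end of chilling: transfer into the glasshouse / out of
#'   storage.
#' @param storage_temp constant storage temperature in degrees C;
#'   required for (and only for) artificial treatments. Default 2, the
#'   midpoint of a 0--4 degree cold store.
#' @return an object of class `treatment`.
#' @export
treatment <- function(id, mode = c("natural", "artificial"),
                      chill_start, chill_end, storage_temp = NULL) {
  mode <- match.arg(mode)
  chill_start <- as_instant(chill_start)
  chill_end <- as_instant(chill_end)
  if (chill_start > chill_end) {
    abort("chill_start must not be after chill_end", "budchill_input_error")
  }
  if (mode == "artificial") {
    if (is.null(storage_temp)) storage_temp <- 2
    stopifnot_scalar_number(storage_temp, "storage_temp")
  } else if (!is.null(storage_temp)) {
    abort("storage_temp only applies to artificial treatments",
          "budchill_input_error")
  }
  structure(list(id = as.character(id), mode = mode,
                 chill_start = chill_start, chill_end = chill_end,
                 storage_temp = storage_temp),
            class = "treatment")
}

#' Chill accumulated by one treatment
#'
#' Natural treatments integrate hourly weights from the accumulation start
#' (the treatment's `chill_start`, or an explicitly supplied `start`) to
#' the transfer instant; treatments transferred before the start date earn
#' 0 (the blank-control convention). Artificial treatments use the
#' constant-temperature closed form over the whole hours spent in storage.
#'
#' @param trt a [treatment()].
#' @param model a [chill_hours()] or [chill_units()] model.
#' @param series an [hourly_series()] covering the natural treatment's
#'   window; ignored for artificial treatments.
#' @param start optional accumulation start overriding `trt$chill_start`
#'   for natural treatments (e.g. a detected start date).
#' @param ... passed to [accumulate_chill()].
#' @return total chill (numeric).
#' @export
treatment_accumulation <- function(trt, model, series = NULL, start = NULL,
                                   ...) {
  stopifnot(inherits(trt, "treatment"), inherits(model, "chill_model"))
  if (trt$mode == "artificial") {
    hours <- floor(as.numeric(difftime(trt$chill_end, trt$chill_start,
                                       units = "hours")))
    return(constant_chill(trt$storage_temp, hours, model))
  }
  if (is.null(series)) {
    abort(sprintf("natural treatment %s needs an hourly temperature series",
                  trt$id),
          "budchill_missing_data_error")
  }
  start <- if (is.null(start)) trt$chill_start else as_instant(start)
  if (trt$chill_end <= start) return(0)
  as.numeric(accumulate_chill(series, start, trt$chill_end, model, ...))
}

#' Built-in morphological index direction registry
#'
#' The sprouting/growth/flowering indices scored per treatment, with the
#' direction in which larger values mean better performance. Most indices
#' (budbreak percentages, stem and flower counts, plant size) are
#' higher-is-better; waiting times and abortion rates (DEA, PAF, DFS, DFF)
#' are lower-is-better. The registry is also shipped as
#' `extdata/index_directions.csv`.
#'
#' @return data frame with columns `index_code` and `higher_is_better`.
#' @export
index_directions <- function() {
  path <- system.file("extdata", "index_directions.csv",
                      package = "budchill", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

check_morpho <- function(morpho) {
  need <- c("treatment_id", "index_code", "replicate", "value")
  if (!is.data.frame(morpho) || nrow(morpho) == 0L ||
      !all(need %in% names(morpho))) {
    abort(paste("morphology table must be a non-empty data frame with",
                "columns treatment_id, index_code, replicate, value"),
          "budchill_config_error")
  }
  invisible(morpho)
}

#' Adequacy rules for morphology-based CR calls
#'
#' A rule set names the indices and thresholds that decide whether a
#' treatment received adequate chill. The default requires a final
#' budbreak percentage (FBP) of at least 95 and at least one opening
#' flower (NOF > 0), reproducing the qualitative calls made from the
#' morphology tables.
#'
#' @param rules data frame with columns `index_code`, `op` (one of
#'   `">="`, `">"`, `"<="`, `"<"`), `value`.
#' @return the validated rule data frame (class `adequacy_rules`).
#' @export
adequacy_rules <- function(rules = data.frame(
                             index_code = c("FBP", "NOF"),
                             op = c(">=", ">"),
                             value = c(95, 0),
                             stringsAsFactors = FALSE)) {
  stopifnot(is.data.frame(rules),
            all(c("index_code", "op", "value") %in% names(rules)))
  if (nrow(rules) == 0L) {
    abort("adequacy rule set must name at least one index",
          "budchill_config_error")
  }
  if (!all(rules$op %in% c(">=", ">", "<=", "<"))) {
    abort("adequacy rule op must be one of >=, >, <=, <",
          "budchill_config_error")
  }
  class(rules) <- c("adequacy_rules", "data.frame")
  rules
}

#' Label treatments adequate or inadequate from morphology
#'
#' Averages each index over replicates per treatment and applies every
#' rule; a treatment is `adequate` only if all rules hold. The rules used
#' are attached to the result so reports can echo them.
#'
#' @param morpho long-format morphology table: columns `treatment_id`,
#'   `index_code`, `replicate`, `value`.
#' @param rules an [adequacy_rules()] rule set.
#' @return named character vector (`"adequate"`/`"inadequate"`) keyed by
#'   treatment id, with attribute `rules`.
#' @export
adequacy_labels <- function(morpho, rules = adequacy_rules()) {
  check_morpho(morpho)
  rules <- adequacy_rules(rules)
  missing_idx <- setdiff(rules$index_code, unique(morpho$index_code))
  if (length(missing_idx)) {
    abort(sprintf("rule index(es) absent from morphology table: %s",
                  paste(missing_idx, collapse = ", ")),
          "budchill_config_error")
  }
  ids <- unique(morpho$treatment_id)
  means <- aggregate(value ~ treatment_id + index_code, data = morpho,
                     FUN = mean)
  lab <- vapply(ids, function(id) {
    ok <- vapply(seq_len(nrow(rules)), function(r) {
      v <- means$value[means$treatment_id == id &
                         means$index_code == rules$index_code[r]]
      if (length(v) == 0L) {
        abort(sprintf("treatment %s has no %s measurements", id,
                      rules$index_code[r]),
              "budchill_config_error")
      }
      switch(rules$op[r],
             ">=" = v >= rules$value[r],
             ">"  = v > rules$value[r],
             "<=" = v <= rules$value[r],
             "<"  = v < rules$value[r])
    }, logical(1))
    if (all(ok)) "adequate" else "inadequate"
  }, character(1))
  names(lab) <- ids
  attr(lab, "rules") <- rules
  lab
}

#' Interval estimate of a chilling requirement
#'
#' @param lower,upper endpoints in model units.
#' @param units `"CH"` or `"CU"`.
#' @param lower_open,upper_open endpoint openness flags.
#' @param empty logical: an empty interval (from an intersection with no
#'   overlap).
#' @return object of class `cr_bracket`.
#' @export
cr_bracket <- function(lower, upper, units, lower_open = TRUE,
                       upper_open = FALSE, empty = FALSE) {
  if (!empty) {
    stopifnot_scalar_number(lower, "lower")
    stopifnot_scalar_number(upper, "upper")
    if (lower > upper) abort("lower must be <= upper", "budchill_input_error")
  }
  structure(list(lower = if (empty) NA_real_ else lower,
                 upper = if (empty) NA_real_ else upper,
                 units = units, lower_open = lower_open,
                 upper_open = upper_open, empty = empty),
            class = "cr_bracket")
}

#' @export
format.cr_bracket <- function(x, ...) {
  if (x$empty) return(sprintf("empty bracket (%s)", x$units))
  sprintf("%s%s, %s%s %s",
          if (x$lower_open) "(" else "[",
          format_chill(x$lower), format_chill(x$upper),
          if (x$upper_open) ")" else "]", x$units)
}

#' @export
print.cr_bracket <- function(x, ...) {
  cat("CR bracket:", format(x), "\n")
  invisible(x)
}

#' Is a CR bracket empty?
#' @param x a [cr_bracket()].
#' @return logical.
#' @export
is_empty_bracket <- function(x) {
  stopifnot(inherits(x, "cr_bracket"))
  isTRUE(x$empty)
}

#' Bracket the CR from per-treatment outcomes
#'
#' The chilling requirement lies above the largest chill dose that failed
#' (open endpoint: that dose was observed inadequate) and at or below the
#' smallest dose that succeeded (closed endpoint: that dose was observed
#' adequate). With no inadequate treatment the lower endpoint is 0,
#' closed.
#'
#' @param accumulations named numeric vector of chill totals per
#'   treatment id.
#' @param labels named character vector from [adequacy_labels()].
#' @param units `"CH"` or `"CU"`.
#' @return a [cr_bracket()].
#' @export
bracket_from_outcomes <- function(accumulations, labels, units) {
  ids <- intersect(names(accumulations), names(labels))
  if (length(ids) == 0L) {
    abort("no treatment ids shared between accumulations and labels",
          "budchill_input_error")
  }
  acc <- accumulations[ids]
  lab <- labels[ids]
  adequate <- acc[lab == "adequate"]
  inadequate <- acc[lab == "inadequate"]
  if (length(adequate) == 0L) {
    abort("no adequate treatment: CR exceeds maximum applied chill",
          "budchill_estimation_error")
  }
  if (length(inadequate) == 0L) {
    return(cr_bracket(0, min(adequate), units, lower_open = FALSE))
  }
  cr_bracket(max(inadequate), min(adequate), units, lower_open = TRUE)
}

#' Intersect two CR brackets
#'
#' Combines independent interval evidence (e.g. natural and artificial
#' experiments) for the same model units. Endpoint openness propagates
#' from whichever bracket supplies the binding endpoint; ties take the
#' stricter (open) flag. Returns an empty bracket when the intervals do
#' not overlap.
#'
#' @param a,b [cr_bracket()] objects with matching `units`.
#' @return a [cr_bracket()], possibly empty.
#' @export
intersect_brackets <- function(a, b) {
  stopifnot(inherits(a, "cr_bracket"), inherits(b, "cr_bracket"))
  if (!identical(a$units, b$units)) {
    abort(sprintf("cannot intersect %s bracket with %s bracket",
                  a$units, b$units),
          "budchill_unit_error")
  }
  if (a$empty || b$empty) return(cr_bracket(NA, NA, a$units, empty = TRUE))
  if (a$lower > b$lower) {
    lower <- a$lower; lower_open <- a$lower_open
  } else if (b$lower > a$lower) {
    lower <- b$lower; lower_open <- b$lower_open
  } else {
    lower <- a$lower; lower_open <- a$lower_open || b$lower_open
  }
  if (a$upper < b$upper) {
    upper <- a$upper; upper_open <- a$upper_open
  } else if (b$upper < a$upper) {
    upper <- b$upper; upper_open <- b$upper_open
  } else {
    upper <- a$upper; upper_open <- a$upper_open || b$upper_open
  }
  if (lower > upper || (lower == upper && (lower_open || upper_open))) {
    return(cr_bracket(NA, NA, a$units, empty = TRUE))
  }
  cr_bracket(lower, upper, a$units, lower_open, upper_open)
}

#' Composite morphological ranking of treatments
#'
#' Replaces per-index significance testing with a transparent composite
#' score: each index's treatment means are min--max scaled to `[0, 1]`,
#' lower-is-better indices are inverted, and treatments are ranked by the
#' weighted mean of scaled indices. All-constant indices carry no
#' information and are dropped with a warning. Ties rank the treatment
#' with less accumulated chill first (the cheaper dose wins).
#'
#' @param morpho long-format morphology table (see [adequacy_labels()]).
#' @param accumulations named chill totals per treatment (for tie-breaks
#'   and reporting).
#' @param weights optional named non-negative weights per index; default
#'   equal weight.
#' @param directions direction registry, default [index_directions()].
#' @return data frame (class `composite_rank`) with columns
#'   `treatment_id`, `chill`, `score`, `rank`; attribute `optimal` names
#'   the top-ranked treatment.
#' @export
composite_rank <- function(morpho, accumulations, weights = NULL,
                           directions = index_directions()) {
  check_morpho(morpho)
  means <- aggregate(value ~ treatment_id + index_code, data = morpho,
                     FUN = mean)
  idx <- unique(means$index_code)
  unknown <- setdiff(idx, directions$index_code)
  if (length(unknown)) {
    abort(sprintf("no direction registered for index(es): %s",
                  paste(unknown, collapse = ", ")),
          "budchill_config_error")
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(idx)), idx)
  if (any(weights < 0) || all(weights == 0)) {
    abort("weights must be non-negative with at least one positive",
          "budchill_config_error")
  }
  ids <- unique(means$treatment_id)
  scaled <- matrix(NA_real_, nrow = length(ids), ncol = length(idx),
                   dimnames = list(ids, idx))
  for (j in idx) {
    v <- means$value[match(paste(ids, j),
                           paste(means$treatment_id, means$index_code))]
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) {
      warning(sprintf("index %s constant across treatments; dropped", j),
              call. = FALSE)
      next
    }
    s <- (v - rng[1L]) / diff(rng)
    hib <- directions$higher_is_better[directions$index_code == j]
    scaled[, j] <- if (hib) s else 1 - s
  }
  keep <- colnames(scaled)[colSums(is.na(scaled)) < nrow(scaled)]
  if (length(keep) == 0L) {
    abort("all indices constant across treatments; nothing to rank",
          "budchill_estimation_error")
  }
  w <- weights[keep]
  w[is.na(w)] <- 0
  score <- as.numeric(scaled[, keep, drop = FALSE] %*% w / sum(w))
  chill <- accumulations[ids]
  ord <- order(-score, chill, ids)
  out <- data.frame(treatment_id = ids, chill = as.numeric(chill),
                    score = score)[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "optimal") <- out$treatment_id[1L]
  class(out) <- c("composite_rank", "data.frame")
  out
}

#' Checkpoint series of accumulated chill
#'
#' Ordered (date, accumulated chill) pairs for one winter: the "key time
#' points" at which cumulative chill is read off when the chill model is
#' used in reverse to date CR fulfillment.
#'
#' @param date `Date` vector (or coercible), strictly increasing.
#' @param chill accumulated chill at each date, non-decreasing.
#' @param units `"CH"` or `"CU"`.
#' @param winter label for the winter.
#' @return data frame of class `checkpoint_series`.
#' @export
checkpoint_series <- function(date, chill, units = "CH", winter = "") {
  date <- as.Date(date)
  if (anyNA(date) || anyNA(chill)) {
    abort("checkpoint dates and chill must be complete",
          "budchill_input_error")
  }
  if (length(date) == 0L) {
    abort("empty checkpoint series", "budchill_input_error")
  }
  if (is.unsorted(date, strictly = TRUE)) {
    abort("checkpoint dates must be strictly increasing",
          "budchill_input_error")
  }
  if (is.unsorted(chill)) {
    abort("accumulated chill must be non-decreasing over checkpoints",
          "budchill_input_error")
  }
  out <- data.frame(date = date, chill = as.numeric(chill))
  attr(out, "units") <- units
  attr(out, "winter") <- winter
  class(out) <- c("checkpoint_series", "data.frame")
  out
}

#' Build a checkpoint series from an hourly record
#'
#' Accumulates chill from `start` to each checkpoint date (at `at_hour`
#' o'clock) with [accumulate_chill()].
#'
#' @param series an [hourly_series()].
#' @param dates checkpoint dates.
#' @param start accumulation start instant.
#' @param model a chill model.
#' @param at_hour clock hour of each checkpoint (default 10, transfer
#'   time).
#' @param winter label.
#' @param ... passed to [accumulate_chill()].
#' @return a [checkpoint_series()].
#' @export
checkpoints_from_series <- function(series, dates, start, model,
                                    at_hour = 10, winter = "", ...) {
  dates <- as.Date(dates)
  start <- as_instant(start)
  chill <- vapply(seq_along(dates), function(i) {
    end <- as.POSIXct(sprintf("%s %02d:00:00", dates[i], at_hour),
                      tz = "UTC")
    if (end <= start) return(0)
    as.numeric(accumulate_chill(series, start, end, model, ...))
  }, numeric(1))
  checkpoint_series(dates, chill, units = model$units, winter = winter)
}

#' Date at which a winter fulfills a chilling requirement
#'
#' "Reverse use" of a chill model: the earliest checkpoint whose
#' accumulated chill meets or exceeds the CR value.
#'
#' @param checkpoints a [checkpoint_series()].
#' @param cr chilling requirement in the series' units, `>= 0`.
#' @return the fulfillment `Date`, or `NA` if the winter never reaches
#'   `cr`.
#' @export
estimate_fulfillment <- function(checkpoints, cr) {
  stopifnot(inherits(checkpoints, "checkpoint_series"))
  stopifnot_scalar_number(cr, "cr")
  if (cr < 0) abort("cr must be >= 0", "budchill_input_error")
  hit <- which(checkpoints$chill >= cr)
  if (length(hit) == 0L) return(as.Date(NA))
  checkpoints$date[hit[1L]]
}

#' Delay of CR fulfillment between two winters
#'
#' Calendar-day difference between the fulfillment dates of winter `b`
#' and winter `a` at the same CR, compared on aligned calendars: the two
#' winters' checkpoint patterns correspond date-for-date, so the years
#' between them are removed by aligning their first checkpoints before
#' differencing. Also reported in whole weeks (days / 7 rounded to
#' nearest; a 14-day checkpoint gap is "2 weeks").
#'
#' @param checkpoints_a,checkpoints_b [checkpoint_series()] objects for
#'   the two winters (matching checkpoint calendar pattern).
#' @param cr chilling requirement.
#' @return object of class `fulfillment_delay`: list with `date_a`,
#'   `date_b`, `days` (b minus a, aligned), `weeks`.
#' @export
fulfillment_delay <- function(checkpoints_a, checkpoints_b, cr) {
  da <- estimate_fulfillment(checkpoints_a, cr)
  db <- estimate_fulfillment(checkpoints_b, cr)
  if (is.na(da) || is.na(db)) {
    abort("CR never fulfilled in at least one winter; delay undefined",
          "budchill_undefined_delay_error")
  }
  offset <- as.numeric(checkpoints_b$date[1L] - checkpoints_a$date[1L])
  days <- as.numeric(db - da) - offset
  structure(list(date_a = da, date_b = db, days = days,
                 weeks = round(days / 7)),
            class = "fulfillment_delay")
}

#' @export
print.fulfillment_delay <- function(x, ...) {
  cat(sprintf("CR fulfillment: %s vs %s; delay %+d day(s) = %+d week(s)\n",
              format(x$date_a), format(x$date_b), as.integer(x$days),
              as.integer(x$weeks)))
  invisible(x)
}

#' Estimate a chilling requirement from one experiment
#'
#' The central estimator: given a set of treatments, their morphology
#' table and a chill model (plus an hourly series for natural
#' treatments), computes per-treatment chill accumulations, applies the
#' adequacy rules, and brackets the CR between the largest inadequate and
#' smallest adequate dose. Also ranks treatments by composite morphology
#' score to identify the optimal dose.
#'
#' @param treatments list of [treatment()] objects.
#' @param morpho long-format morphology table.
#' @param model a [chill_hours()] or [chill_units()] model.
#' @param series hourly series for natural treatments (optional
#'   otherwise).
#' @param start accumulation start for natural treatments (optional; see
#'   [treatment_accumulation()]).
#' @param rules an [adequacy_rules()] rule set.
#' @param rank logical: also compute the composite ranking (requires
#'   direction registrations for every index present).
#' @param ... passed to [accumulate_chill()].
#' @return object of class `cr_fit`: list with `accumulations`, `labels`,
#'   `bracket`, `ranking` (or `NULL`), `model`, `rules`.
#' @examples
#' trts <- lapply(1:5, function(k)
#'   treatment(sprintf("T%d", k), "artificial",
#'             "2013-11-29 09:00", sprintf("2013-12-%02d 09:00", 5 + 7 * k)))
#' @export
estimate_cr <- function(treatments, morpho, model, series = NULL,
                        start = NULL, rules = adequacy_rules(),
                        rank = TRUE, ...) {
  stopifnot(is.list(treatments), length(treatments) > 0L,
            all(vapply(treatments, inherits, logical(1), "treatment")))
  acc <- vapply(treatments, treatment_accumulation, numeric(1),
                model = model, series = series, start = start, ...)
  names(acc) <- vapply(treatments, `[[`, character(1), "id")
  labels <- adequacy_labels(morpho, rules)
  bracket <- bracket_from_outcomes(acc, labels, model$units)
  ranking <- if (rank) composite_rank(morpho, acc) else NULL
  structure(list(accumulations = acc, labels = labels, bracket = bracket,
                 ranking = ranking, model = model,
                 rules = attr(labels, "rules")),
            class = "cr_fit")
}

#' @export
print.cr_fit <- function(x, ...) {
  cat(sprintf("Chilling-requirement fit (%s model, %d treatments)\n",
              x$model$units, length(x$accumulations)))
  cat("  CR bracket:", format(x$bracket), "\n")
  if (!is.null(x$ranking)) {
    cat("  Optimal treatment:", attr(x$ranking, "optimal"),
        sprintf("(%s %s)\n",
                format_chill(x$accumulations[[attr(x$ranking, "optimal")]]),
                x$model$units))
  }
  invisible(x)
}

#' @export
summary.cr_fit <- function(object, ...) {
  tab <- data.frame(
    treatment_id = names(object$accumulations),
    chill = as.numeric(object$accumulations),
    label = as.character(object$labels[names(object$accumulations)])
  )
  if (!is.null(object$ranking)) {
    tab$rank <- object$ranking$rank[match(tab$treatment_id,
                                          object$ranking$treatment_id)]
  }
  structure(list(table = tab, bracket = object$bracket,
                 rules = object$rules, units = object$model$units),
            class = "summary.cr_fit")
}

#' @export
print.summary.cr_fit <- function(x, ...) {
  cat(sprintf("CR evaluation (%s)\n", x$units))
  print(x$table, row.names = FALSE)
  cat("Adequacy rules:\n")
  print(as.data.frame(x$rules), row.names = FALSE)
  cat("Bracket:", format(x$bracket), "\n")
  invisible(x)
}

#' @export
coef.cr_fit <- function(object, ...) {
  c(lower = object$bracket$lower, upper = object$bracket$upper)
}
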