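#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()],
#' which exercises every analysis stage on a self-contained synthetic
#' two-winter scenario: a reference winter and a warmer winter whose
#' CR-fulfillment is delayed, weekly refrigerated-storage treatments for
#' bracket estimation, and a paired expression data set with a planted
#' lag. Every threshold is echoed into the output report. Unknown keys
#' are rejected.
#'
#' @param ... overrides for the default keys: `seed`, `stages` (subset of
#'   `c("accumulate", "brackets", "intersection", "fulfillment",
#'   "screening", "congruence")`), `model` (`"CH"` or `"CU"`),
#'   `warm_offset` (degrees C added to winter b), `true_cr`,
#'   `storage_temp`, `storage_weeks`, `start_threshold_c`,
#'   `persistence_days`, `fold_threshold`, `min_peak`, `pseudocount`,
#'   `r_high`, `r_mid`, `gain`, `max_lag`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    stages = c("accumulate", "brackets", "intersection", "fulfillment",
               "screening", "congruence"),
    model = "CH",
    warm_offset = 1,
    true_cr = 600,
    storage_temp = 2,
    storage_weeks = 0:5,
    start_threshold_c = 7.2,
    persistence_days = 3,
    fold_threshold = 4,
    min_peak = 1,
    pseudocount = 0.1,
    r_high = 0.8,
    r_mid = 0.5,
    gain = 0.2,
    max_lag = 2
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          "budchill_config_error")
  }
  cfg <- utils::modifyList(defaults, override)
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad)) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
          "budchill_config_error")
  }
  if (!cfg$model %in% c("CH", "CU")) {
    abort("model must be 'CH' or 'CU'", "budchill_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on the synthetic scenario
#'
#' Executes the configured stages in order — chill accumulation, CR
#' brackets (natural and artificial), bracket intersection, reverse-use
#' fulfillment and delay, expression screening, congruence — and returns
#' a report bundle. Reruns with an identical configuration produce
#' identical results.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory: result tables (delimited text)
#'   and a structured JSON report are written there.
#' @return list of class `pipeline_report` with one element per executed
#'   stage plus `config` (all thresholds echoed) and `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- if (config$model == "CH") chill_hours() else chill_units()
  report <- list(config = unclass(config), seed = config$seed)
  run <- function(stage) stage %in% config$stages

  winter_a <- simulate_winter(winter_config(seed = config$seed,
                                            season_label = "winter_a"))
  # paired-weather design: winter b shares winter a's weather noise and
  # differs only by the uniform warm offset, which typically pushes CR
  # fulfillment one biweekly checkpoint later
  winter_b <- simulate_winter(winter_config(seed = config$seed,
                                            warm_offset = config$warm_offset,
                                            season_label = "winter_b"))
  start_a <- detect_start_date(winter_a, config$start_threshold_c,
                               config$persistence_days)
  start_b <- detect_start_date(winter_b, config$start_threshold_c,
                               config$persistence_days)
  cp_dates_a <- seq(as.Date(start_a) + 14, by = 14, length.out = 6)
  cp_a <- checkpoints_from_series(winter_a, cp_dates_a, start_a, model,
                                  winter = "winter_a")
  cp_b <- checkpoints_from_series(winter_b, cp_dates_a, start_b, model,
                                  winter = "winter_b")

  if (run("accumulate")) {
    windows <- data.frame(
      start = format(start_a, "%Y-%m-%dT%H:%M:%S"),
      end = format(as.POSIXct(paste(cp_dates_a, "10:00:00"), tz = "UTC"),
                   "%Y-%m-%dT%H:%M:%S"))
    report$accumulate <- accumulation_report(winter_a, windows, model)
  }

  trts <- lapply(config$storage_weeks, function(w) {
    treatment(sprintf("store-%dw", w), "artificial",
              "2013-11-29 09:00:00",
              as.POSIXct("2013-11-29 09:00:00", tz = "UTC") +
                w * 7 * 24 * 3600,
              storage_temp = config$storage_temp)
  })
  acc <- vapply(trts, treatment_accumulation, numeric(1), model = model)
  names(acc) <- vapply(trts, `[[`, character(1), "id")
  fit <- NULL
  if (run("brackets") || run("intersection")) {
    morpho <- simulate_morphology(
      acc, morpho_sim_config(true_cr = config$true_cr,
                             seed = config$seed + 2))
    fit <- estimate_cr(trts, morpho, model)
    report$brackets <- list(
      artificial = format(fit$bracket),
      accumulations = data.frame(treatment_id = names(acc),
                                 chill = as.numeric(acc)),
      labels = data.frame(treatment_id = names(fit$labels),
                          label = as.character(fit$labels)),
      optimal = attr(fit$ranking, "optimal"))
  }
  if (run("intersection")) {
    # natural-evidence bracket from the simulated winter's checkpoints,
    # labelled by the same planted CR
    nat_acc <- stats::setNames(cp_a$chill, sprintf("nat-%d", seq_len(6)))
    nat_lab <- ifelse(nat_acc >= config$true_cr, "adequate", "inadequate")
    nat_bracket <- bracket_from_outcomes(nat_acc, nat_lab, model$units)
    inter <- intersect_brackets(fit$bracket, nat_bracket)
    report$intersection <- list(natural = format(nat_bracket),
                                artificial = format(fit$bracket),
                                intersection = format(inter))
  }
  delay <- NULL
  if (run("fulfillment") || run("congruence")) {
    cr_use <- if (!is.null(fit) && !fit$bracket$empty) {
      fit$bracket$upper
    } else {
      config$true_cr
    }
    delay <- fulfillment_delay(cp_a, cp_b, cr_use)
    if (run("fulfillment")) {
      report$fulfillment <- list(
        cr = cr_use,
        checkpoints_a = data.frame(date = format(cp_a$date),
                                   chill = cp_a$chill),
        checkpoints_b = data.frame(date = format(cp_b$date),
                                   chill = cp_b$chill),
        date_a = format(delay$date_a), date_b = format(delay$date_b),
        delay_days = delay$days, delay_weeks = delay$weeks)
    }
  }
  expr <- NULL
  if (run("screening") || run("congruence")) {
    cp_idx_a <- which(cp_a$date == as.Date(if (is.null(delay)) cp_a$date[4]
                                           else delay$date_a))
    cp_idx_b <- which(cp_b$date == as.Date(if (is.null(delay)) cp_b$date[5]
                                           else delay$date_b))
    expr <- simulate_expression_pair(
      expression_sim_config(seed = config$seed + 3),
      fulfillment_checkpoint_a = cp_idx_a,
      fulfillment_checkpoint_b = cp_idx_b)
  }
  if (run("screening")) {
    kept <- differential_screen(expr$matrix_a,
                                fold_threshold = config$fold_threshold,
                                min_peak = config$min_peak,
                                pseudocount = config$pseudocount)
    report$screening <- list(criteria = attr(kept, "criteria"),
                             n_screened = length(kept),
                             gene_ids = as.character(kept))
  }
  if (run("congruence")) {
    cg <- congruence_screen(expr$matrix_a, expr$matrix_b,
                            fulfillment_delay_days = delay$days,
                            checkpoint_spacing_days = 14,
                            max_lag = config$max_lag,
                            r_high = config$r_high, r_mid = config$r_mid,
                            gain = config$gain)
    cg$truth_class <- expr$truth$class[match(cg$gene_id,
                                             expr$truth$gene_id)]
    report$congruence <- cg
  }
  class(report) <- "pipeline_report"
  if (!is.null(output_dir)) write_pipeline_report(report, output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  stages <- setdiff(names(x), c("config", "seed"))
  cat(sprintf("Pipeline report (seed %s): stages %s\n", x$seed,
              paste(stages, collapse = ", ")))
  if (!is.null(x$intersection)) {
    cat("  CR bracket intersection:", x$intersection$intersection, "\n")
  }
  if (!is.null(x$fulfillment)) {
    cat(sprintf("  Fulfillment delay: %+d day(s) (%+d week(s))\n",
                as.integer(x$fulfillment$delay_days),
                as.integer(x$fulfillment$delay_weeks)))
  }
  if (!is.null(x$congruence)) {
    cat(sprintf("  CR-congruent genes: %d of %d\n",
                sum(x$congruence$congruent, na.rm = TRUE),
                nrow(x$congruence)))
  }
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Writes each tabular stage result as delimited text plus the whole
#' report as structured JSON, and a run log (versions, seed, thresholds).
#' Result tables are deterministic for a fixed configuration; only the
#' log carries a wall-clock timestamp.
#'
#' @param report a [run_pipeline()] result.
#' @param output_dir directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, output_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(output_dir, name), sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$accumulate)) wt(report$accumulate, "accumulation.csv")
  if (!is.null(report$brackets)) {
    wt(report$brackets$accumulations, "treatment_chill.csv")
    wt(report$brackets$labels, "adequacy_labels.csv")
  }
  if (!is.null(report$congruence)) wt(report$congruence, "congruence.csv")
  body <- unclass(report)
  body$congruence <- if (!is.null(report$congruence)) report$congruence
  jsonlite::write_json(body, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", force = TRUE)
  log <- c(sprintf("budchill %s",
                   as.character(utils::packageVersion("budchill"))),
           sprintf("R %s", getRversion()),
           sprintf("run at %s", format(Sys.time())),
           sprintf("seed %s", report$seed),
           "thresholds:",
           utils::capture.output(utils::str(report$config)))
  writeLines(log, file.path(output_dir, "run.log"))
  invisible(output_dir)
}
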