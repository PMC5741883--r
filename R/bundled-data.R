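#' Bundled key-time-point chill accumulations
#'
#' Per-interval chilling-hour accumulations between the six bud-sampling
#' checkpoints of the two study winters (2012--2013 and 2015--2016,
#' Hangzhou), as printed; cumulative sums give the accumulated chill at
#' each key time point. These are the inputs of the reverse-use
#' fulfillment estimate.
#'
#' @param winter `"2012-2013"` or `"2015-2016"`.
#' @return a [checkpoint_series()] of cumulative chilling hours.
#' @examples
#' estimate_fulfillment(key_point_checkpoints("2012-2013"), cr = 672)
#' @export
key_point_checkpoints <- function(winter = c("2012-2013", "2015-2016")) {
  winter <- match.arg(winter)
  path <- system.file("extdata", "chill_key_points.csv",
                      package = "budchill", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$winter == winter, , drop = FALSE]
  checkpoint_series(as.Date(tab$checkpoint_date), cumsum(tab$interval_ch),
                    units = "CH", winter = winter)
}

#' Bundled per-treatment chill accumulations
#'
#' The published chilling-hour and chilling-unit totals of the eight
#' natural (2012--2013) and six refrigerated-storage (2013--2014)
#' treatments, used as worked-example inputs for bracket estimation.
#'
#' @return data frame with columns `treatment_id`, `mode`,
#'   `transfer_date`, `ch`, `cu`.
#' @export
published_treatment_chill <- function() {
  path <- system.file("extdata", "treatment_chill.csv",
                      package = "budchill", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$transfer_date <- as.Date(out$transfer_date)
  out
}

#' Bundled per-homolog counts of screened candidate genes
#'
#' The printed tally of temperature- and photoperiod-associated unigenes
#' grouped by their closest homolog (heat-shock families pooled in one
#' row; unigenes without a homolog name under "No Arabidopsis gene
#' name").
#'
#' @return data frame with columns `abbreviation`, `full_name`, `n`.
#' @export
homolog_count_table <- function() {
  path <- system.file("extdata", "homolog_counts.csv",
                      package = "budchill", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
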