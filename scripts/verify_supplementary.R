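#!/usr/bin/env Rscript
# Optional verification against the real 2012-2013 hourly temperature
# record (a download-only supplement, not bundled with the package).
#
# Given that record as delimited text with columns `timestamp`
# (ISO 8601, hourly) and `temp_c`, this script recomputes the natural
# chill-hour accumulation of each 2012-2013 treatment window: from the
# accumulation start (00:00 Dec 8, 2012, when the daily mean had
# steadily passed below 7.2 degC) to 10:00 of each transfer day. With
# the full record, the Tre. 1-2 window (to Dec 10) totals 46.00 CHs and
# the remaining treatments follow the published accumulation table.
#
# Usage:
#   Rscript scripts/verify_supplementary.R --temps <path> [--end <iso date>]

suppressPackageStartupMessages({
  library(optparse)
  library(budchill)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--temps", type = "character",
              help = "hourly temperature table (timestamp,temp_c)"),
  make_option("--start", type = "character",
              default = "2012-12-08 00:00:00",
              help = "accumulation start [default %default]")
)))

if (is.null(opts$temps)) stop("--temps is required", call. = FALSE)

series <- read_temperature_table(opts$temps, season_label = "2012-2013")
model <- chill_hours()
start <- as.POSIXct(opts$start, tz = "UTC")

transfers <- data.frame(
  treatment = c("Tre. 1-2", "Tre. 1-3", "Tre. 1-4", "Tre. 1-5",
                "Tre. 1-6", "Tre. 1-7", "Tre. 1-8"),
  date = as.Date(c("2012-12-10", "2012-12-24", "2013-01-07", "2013-01-21",
                   "2013-02-04", "2013-02-25", "2013-03-11"))
)

last <- as.Date(series$timestamp[nrow(series)])
cat(sprintf("Series: %d records, start rule %s\n", nrow(series),
            format(start)))
for (i in seq_len(nrow(transfers))) {
  if (transfers$date[i] > last) next
  end <- as.POSIXct(paste(transfers$date[i], "10:00:00"), tz = "UTC")
  tot <- accumulate_chill(series, start, end, model,
                          interpolate_gaps = TRUE)
  cat(sprintf("%s (to %s 10:00): %s CH over %d h (%d interpolated)\n",
              transfers$treatment[i], transfers$date[i],
              sprintf("%.2f", round_half_up(as.numeric(tot))),
              attr(tot, "n_hours"), attr(tot, "n_flagged")))
}
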