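# fixture builders shared across test files; everything is generated in
# code so the suite carries no data files

# constant-temperature hourly series of `hours` records
const_series <- function(temp, hours, start = "2012-12-01 00:00:00") {
  ts <- seq(as.POSIXct(start, tz = "UTC"), by = "hour", length.out = hours)
  hourly_series(ts, rep(temp, hours), season_label = "const")
}

# series whose daily means follow `means` (flat within each day)
daily_mean_series <- function(means, start_date = "2012-12-01") {
  ts <- seq(as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC"),
            by = "hour", length.out = 24 * length(means))
  hourly_series(ts, rep(means, each = 24), season_label = "daily")
}

# minimal morphology table: one FBP and one NOF value per treatment
toy_morpho <- function(fbp, nof, ids = names(fbp)) {
  rbind(
    data.frame(treatment_id = ids, index_code = "FBP", replicate = 1L,
               value = as.numeric(fbp)),
    data.frame(treatment_id = ids, index_code = "NOF", replicate = 1L,
               value = as.numeric(nof))
  )
}

# annotation table for keyword tests
toy_annotations <- function() {
  data.frame(
    gene_id = c("g_cor", "g_lhca", "g_ref", "g_soc", "g_none"),
    homolog_locus = c("AT1G20440", "AT1G19150", "AT4G16720", "AT2G45660",
                      NA),
    homolog_name = c("COR47", "LHCA6", "RPL15A", "SOC1", ""),
    description = c(
      "COLD-REGULATED 47",
      "PHOTOSYSTEM I LIGHT HARVESTING COMPLEX GENE 6",
      "Ribosomal protein L23/L15e family protein",
      "AGAMOUS-LIKE 20 flowering integrator",
      "unknown protein"),
    stringsAsFactors = FALSE
  )
}

# independent brute-force lag oracle: plain loops, no shared code path
oracle_best_lag <- function(a, b, max_lag) {
  best <- NULL
  for (L in -max_lag:max_lag) {
    ia <- c(); ib <- c()
    for (i in seq_along(a)) {
      j <- i + L
      if (j >= 1 && j <= length(b)) { ia <- c(ia, i); ib <- c(ib, j) }
    }
    av <- a[ia]; bv <- b[ib]
    if (length(unique(av)) < 2 || length(unique(bv)) < 2) next
    r <- sum((av - mean(av)) * (bv - mean(bv))) /
      sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
    if (is.null(best) || r > best$r + 1e-12 ||
        (abs(r - best$r) <= 1e-12 &&
         (abs(L) < abs(best$lag) ||
          (abs(L) == abs(best$lag) && L < best$lag)))) {
      best <- list(lag = L, r = r)
    }
  }
  best
}
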