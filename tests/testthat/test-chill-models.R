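test_that("chill-hour weight is an inclusive indicator on the 0-7.2 band", {
  m <- chill_hours()
  expect_identical(chill_weight(m, c(0, 7.2, 5)), c(1, 1, 1))
  expect_identical(chill_weight(m, c(-1, 8, 7.21)), c(0, 0, 0))
  excl <- chill_hours(inclusive_bounds = FALSE)
  expect_identical(chill_weight(excl, c(0, 7.2)), c(0, 0))
  expect_error(chill_weight(m, NA_real_), class = "budchill_input_error")
  expect_error(chill_hours(t_low = 8, t_high = 7), class = "budchill_config_error")
})

test_that("chill-unit weight follows the piecewise linear law", {
  m <- chill_units()
  expect_equal(chill_weight(m, 0), 1)
  expect_equal(chill_weight(m, -5), 1)
  expect_equal(chill_weight(m, 12), 0)
  expect_equal(chill_weight(m, 2), 0.879)
  expect_equal(chill_weight(m, 10), -0.0605 * 10 + 1)
  # non-increasing over a fine temperature grid and bounded in [0, 1]
  t <- seq(-20, 30, by = 0.01)
  w <- chill_weight(m, t)
  expect_true(all(diff(w) <= 1e-12))
  expect_true(all(w >= 0 & w <= 1))
  expect_error(chill_units(slope = 0.1), class = "budchill_config_error")
})

test_that("hourly accumulation sums per-hour weights over half-open windows", {
  s <- const_series(5, 24)
  ch <- chill_hours()
  tot <- accumulate_chill(s, "2012-12-01 00:00", "2012-12-02 00:00", ch)
  expect_equal(as.numeric(tot), 24)
  expect_identical(attr(tot, "n_hours"), 24)

  s2 <- const_series(2, 24)
  cu <- chill_units()
  expect_equal(as.numeric(accumulate_chill(s2, "2012-12-01 00:00",
                                           "2012-12-02 00:00", cu)),
               24 * 0.879)

  # additivity over a partition of the window
  s3 <- simulate_winter(winter_config(seed = 42, start = "2012-11-01",
                                      end = "2013-01-15"))
  whole <- accumulate_chill(s3, "2012-11-10 00:00", "2012-12-20 00:00", ch)
  left <- accumulate_chill(s3, "2012-11-10 00:00", "2012-11-29 13:00", ch)
  right <- accumulate_chill(s3, "2012-11-29 13:00", "2012-12-20 00:00", ch)
  expect_equal(as.numeric(whole), as.numeric(left) + as.numeric(right))

  expect_error(accumulate_chill(s, "2012-11-01 00:00", "2012-12-02 00:00", ch),
               class = "budchill_range_error")
})

test_that("per-hour weight never exceeds 1, so totals never exceed window hours", {
  s <- simulate_winter(winter_config(seed = 7, start = "2012-11-01",
                                     end = "2013-01-10"))
  for (m in list(chill_hours(), chill_units())) {
    tot <- accumulate_chill(s, "2012-11-05 00:00", "2012-12-05 00:00", m)
    expect_lte(as.numeric(tot), attr(tot, "n_hours"))
    expect_gte(as.numeric(tot), 0)
  }
})

test_that("gaps inside a window error by default and interpolate on request", {
  ts <- seq(as.POSIXct("2012-12-01 00:00", tz = "UTC"), by = "hour",
            length.out = 48)
  drop <- c(10, 11)  # a 2-hour gap
  s <- hourly_series(ts[-drop], rep(5, 46))
  expect_equal(nrow(series_gaps(s)), 1L)
  expect_error(accumulate_chill(s, ts[1], ts[25], chill_hours()),
               class = "budchill_gap_error")
  tot <- accumulate_chill(s, ts[1], ts[25], chill_hours(),
                          interpolate_gaps = TRUE)
  expect_equal(as.numeric(tot), 24)
  expect_identical(attr(tot, "n_flagged"), 2L)
  # gaps longer than max_gap_hours still refuse to interpolate
  s4 <- hourly_series(ts[-(10:14)], rep(5, 43))
  expect_error(accumulate_chill(s4, ts[1], ts[25], chill_hours(),
                                interpolate_gaps = TRUE, max_gap_hours = 3),
               class = "budchill_gap_error")
})

test_that("constant-temperature closed form reproduces the storage constants", {
  cu <- chill_units()
  ch <- chill_hours()
  hours <- c(0, 168, 336, 504, 672, 840)
  expect_equal(round_half_up(vapply(hours, constant_chill, numeric(1),
                                    t_const = 2, model = cu), 2),
               c(0, 147.67, 295.34, 443.02, 590.69, 738.36))
  expect_equal(vapply(hours, constant_chill, numeric(1),
                      t_const = 2, model = ch),
               c(0, 168, 336, 504, 672, 840))
  expect_error(constant_chill(2, -1, cu), class = "budchill_input_error")
})

test_that("closed form equals hourly accumulation on constant series", {
  for (temp in c(-3, 0, 2, 6.5, 9, 11)) {
    for (m in list(chill_hours(), chill_units())) {
      s <- const_series(temp, 100)
      hourly <- accumulate_chill(s, s$timestamp[1],
                                 s$timestamp[1] + 100 * 3600, m)
      expect_equal(as.numeric(hourly), constant_chill(temp, 100, m),
                   tolerance = 1e-9)
    }
  }
})

test_that("daily means average each date and flag incomplete days", {
  s <- const_series(7, 24)
  dm <- daily_means(s)
  expect_equal(dm$mean_c, 7)
  expect_true(dm$complete)

  alt <- hourly_series(seq(as.POSIXct("2012-12-01 00:00", tz = "UTC"),
                           by = "hour", length.out = 24),
                       rep(c(0, 14), 12))
  expect_equal(daily_means(alt)$mean_c, 7)

  part <- const_series(5, 23)
  dm2 <- daily_means(part)
  expect_false(dm2$complete[1])
  expect_equal(dm2$mean_c[1], 5)
})

test_that("start date is the first persistent drop below threshold", {
  s <- daily_mean_series(rep(5, 5))
  expect_equal(detect_start_date(s, 7.2),
               as.POSIXct("2012-12-01 00:00:00", tz = "UTC"))

  warm <- daily_mean_series(rep(10, 5))
  expect_error(detect_start_date(warm, 7.2),
               class = "budchill_not_found_error")

  mixed <- daily_mean_series(c(9, 8, 7, 6, 6, 6))
  expect_equal(detect_start_date(mixed, 7.2, persistence_days = 3),
               as.POSIXct("2012-12-03 00:00:00", tz = "UTC"))
  # a one-day warm spike resets the persistence count
  spiky <- daily_mean_series(c(6, 6, 9, 6, 6, 6))
  expect_equal(detect_start_date(spiky, 7.2, persistence_days = 3),
               as.POSIXct("2012-12-04 00:00:00", tz = "UTC"))
})

test_that("series constructor rejects sensor errors and disorder", {
  ts <- seq(as.POSIXct("2012-12-01 00:00", tz = "UTC"), by = "hour",
            length.out = 3)
  expect_error(hourly_series(ts, c(5, 60, 5)), class = "budchill_input_error")
  expect_error(hourly_series(ts, c(5, NA, 5)), class = "budchill_input_error")
  expect_error(hourly_series(ts[c(1, 2, 2)], c(5, 5, 5)),
               class = "budchill_duplicate_error")
  expect_error(hourly_series(ts[c(2, 1, 3)], c(5, 5, 5)),
               class = "budchill_duplicate_error")
})

test_that("presentation rounding is half-up at two decimals", {
  expect_equal(round_half_up(147.672), 147.67)
  expect_equal(round_half_up(443.016), 443.02)
  expect_equal(round_half_up(0.005), 0.01)
  expect_equal(round_half_up(-0.005), -0.01)
})
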