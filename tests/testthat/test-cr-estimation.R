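test_that("treatment accumulation covers natural, artificial and blank-control cases", {
  cu <- chill_units()
  ch <- chill_hours()
  art <- treatment("Tre. 2-2", "artificial", "2013-11-29 09:00",
                   "2013-12-06 09:00")
  expect_equal(round_half_up(treatment_accumulation(art, cu)), 147.67)
  art28 <- treatment("Tre. 2-5", "artificial", "2013-11-29 09:00",
                     "2013-12-27 09:00")
  expect_equal(treatment_accumulation(art28, ch), 672)

  s <- const_series(5, 24 * 20, start = "2012-12-08 00:00:00")
  nat <- treatment("Tre. 1-3", "natural", "2012-12-08 00:00",
                   "2012-12-24 10:00")
  expect_equal(treatment_accumulation(nat, ch, series = s),
               16 * 24 + 10)
  # transferred before the accumulation start: blank control earns 0
  blank <- treatment("Tre. 1-1", "natural", "2012-11-26 10:00",
                     "2012-11-26 10:00")
  expect_equal(treatment_accumulation(blank, ch, series = s,
                                      start = "2012-12-08 00:00"), 0)
  expect_error(treatment_accumulation(nat, ch),
               class = "budchill_missing_data_error")
  expect_error(treatment("x", "natural", "2013-01-02", "2013-01-01"),
               class = "budchill_input_error")
})

test_that("adequacy labels apply the configured thresholds", {
  m <- toy_morpho(fbp = c(A = 100, B = 71), nof = c(A = 2, B = 0))
  lab <- adequacy_labels(m)
  expect_identical(unname(lab[c("A", "B")]),
                   c("adequate", "inadequate"))
  expect_s3_class(attr(lab, "rules"), "adequacy_rules")

  # high budbreak but no flower fails the default rule
  m2 <- toy_morpho(fbp = c(C = 98), nof = c(C = 0))
  expect_identical(unname(adequacy_labels(m2)["C"]), "inadequate")

  expect_error(adequacy_labels(data.frame()),
               class = "budchill_config_error")
  bad_rules <- data.frame(index_code = "XYZ", op = ">=", value = 1)
  expect_error(adequacy_labels(m, bad_rules),
               class = "budchill_config_error")
})

test_that("CR bracket spans last-inadequate to first-adequate dose", {
  acc <- c(t1 = 0, t2 = 483, t3 = 738, t4 = 892)
  lab <- c(t1 = "inadequate", t2 = "inadequate", t3 = "adequate",
           t4 = "adequate")
  b <- bracket_from_outcomes(acc, lab, "CH")
  expect_equal(b$lower, 483)
  expect_equal(b$upper, 738)
  expect_true(b$lower_open)
  expect_false(b$upper_open)
  expect_equal(format(b), "(483.00, 738.00] CH")

  all_ok <- bracket_from_outcomes(acc, setNames(rep("adequate", 4),
                                                names(acc)), "CH")
  expect_equal(all_ok$lower, 0)
  expect_false(all_ok$lower_open)
  expect_equal(all_ok$upper, 0)

  expect_error(bracket_from_outcomes(acc, setNames(rep("inadequate", 4),
                                                   names(acc)), "CH"),
               class = "budchill_estimation_error")
})

test_that("bracket intersection reproduces the published interval algebra", {
  nat <- cr_bracket(483, 738, "CH")
  art <- cr_bracket(504, 672, "CH")
  inter <- intersect_brackets(nat, art)
  expect_equal(inter$lower, 504)
  expect_equal(inter$upper, 672)
  expect_false(is_empty_bracket(inter))

  nat_cu <- cr_bracket(615.27, 856.08, "CU")
  art_cu <- cr_bracket(443.02, 590.69, "CU")
  expect_true(is_empty_bracket(intersect_brackets(nat_cu, art_cu)))

  # algebra: idempotent, commutative, nested gives the inner bracket
  expect_equal(intersect_brackets(nat, nat), nat)
  ab <- intersect_brackets(nat, art)
  ba <- intersect_brackets(art, nat)
  expect_equal(ab, ba)
  inner <- cr_bracket(550, 600, "CH")
  expect_equal(intersect_brackets(nat, inner), inner)

  expect_error(intersect_brackets(nat, nat_cu),
               class = "budchill_unit_error")
})

test_that("composite ranking scales indices, honors direction and tie-breaks by chill", {
  acc <- c(A = 100, B = 200, C = 300)
  # identical morphology for all treatments: constant indices dropped,
  # falls back to error since nothing remains
  same <- toy_morpho(fbp = c(A = 90, B = 90, C = 90),
                     nof = c(A = 1, B = 1, C = 1))
  expect_error(suppressWarnings(composite_rank(same, acc)),
               class = "budchill_estimation_error")

  # a single higher-is-better index ranks its argmax first
  one <- data.frame(treatment_id = c("A", "B", "C"), index_code = "NOF",
                    replicate = 1L, value = c(1, 3, 2))
  r <- composite_rank(one, acc)
  expect_identical(attr(r, "optimal"), "B")

  # lower-is-better index inverts: smallest DEA wins
  dea <- data.frame(treatment_id = c("A", "B", "C"), index_code = "DEA",
                    replicate = 1L, value = c(30, 12, 20))
  expect_identical(attr(composite_rank(dea, acc), "optimal"), "B")

  # tie on score resolves toward the lower chill dose
  tie <- data.frame(treatment_id = c("A", "B", "C"), index_code = "NOF",
                    replicate = 1L, value = c(3, 3, 1))
  rt <- composite_rank(tie, c(A = 200, B = 100, C = 50))
  expect_identical(attr(rt, "optimal"), "B")
})

test_that("saturating dose-response morphology ranks the first saturated dose optimal", {
  acc <- setNames(seq(0, 840, by = 168), paste0("w", 0:5))
  # steep response: every dose past the requirement saturates to machine
  # precision, so the tie-break must pick the cheapest saturated dose
  cfg <- morpho_sim_config(true_cr = 400, steepness = 0.5, seed = 5)
  # noiseless: zero out index noise
  cfg$indices$noise_sd <- 0
  morpho <- simulate_morphology(acc, cfg)
  r <- composite_rank(morpho, acc)
  # brute-force expectation: all doses past saturation score equally,
  # tie-break selects the cheapest saturated dose (504 CH)
  expect_identical(attr(r, "optimal"), "w3")
})

test_that("reverse-use fulfillment finds the earliest sufficient checkpoint", {
  cp_a <- key_point_checkpoints("2012-2013")
  cp_b <- key_point_checkpoints("2015-2016")
  expect_equal(cp_a$chill, c(0, 103, 307, 795, 949, 1227))
  expect_equal(cp_b$chill, c(33, 161, 268, 599, 857, 1084))
  expect_equal(estimate_fulfillment(cp_a, 672), as.Date("2013-01-21"))
  expect_equal(estimate_fulfillment(cp_b, 672), as.Date("2016-02-04"))
  expect_equal(estimate_fulfillment(cp_a, 0), cp_a$date[1])
  expect_true(is.na(estimate_fulfillment(cp_a, 2000)))

  d <- fulfillment_delay(cp_a, cp_b, 672)
  expect_equal(d$days, 14)
  expect_equal(d$weeks, 2)
  expect_equal(fulfillment_delay(cp_a, cp_a, 672)$days, 0)
  expect_error(fulfillment_delay(cp_a, cp_b, 2000),
               class = "budchill_undefined_delay_error")
})

test_that("fulfillment date is monotone in the requirement", {
  cp <- key_point_checkpoints("2012-2013")
  crs <- sort(runif(25, 0, 1300))
  dates <- as.numeric(vapply(crs, function(cr)
    as.numeric(estimate_fulfillment(cp, cr)), numeric(1)))
  expect_true(all(diff(dates) >= 0, na.rm = TRUE))
})

test_that("fulfillment agrees between precomputed and on-demand checkpoints", {
  s <- simulate_winter(winter_config(seed = 11))
  start <- detect_start_date(s, 7.2)
  dates <- seq(as.Date(start) + 14, by = 14, length.out = 6)
  cp <- checkpoints_from_series(s, dates, start, chill_hours())
  expect_false(is.unsorted(cp$chill))
  cr <- cp$chill[4] - 1
  direct <- dates[which(vapply(dates, function(d) {
    as.numeric(accumulate_chill(s, start,
                                as.POSIXct(paste(d, "10:00:00"),
                                           tz = "UTC"),
                                chill_hours())) >= cr
  }, logical(1)))[1]]
  expect_equal(estimate_fulfillment(cp, cr), direct)
})

test_that("estimate_cr brackets a planted requirement from noiseless morphology", {
  model <- chill_hours()
  trts <- lapply(0:5, function(w)
    treatment(sprintf("w%d", w), "artificial", "2013-11-29 09:00",
              as.POSIXct("2013-11-29 09:00", tz = "UTC") + w * 7 * 86400))
  acc <- vapply(trts, treatment_accumulation, numeric(1), model = model)
  names(acc) <- sprintf("w%d", 0:5)
  cfg <- morpho_sim_config(true_cr = 600, steepness = 0.1, seed = 1)
  cfg$indices$noise_sd <- 0
  fit <- estimate_cr(trts, simulate_morphology(acc, cfg), model)
  expect_s3_class(fit, "cr_fit")
  expect_true(fit$bracket$lower < 600 && fit$bracket$upper >= 600)
  expect_equal(unname(coef(fit)), c(504, 672))
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("FBP", out)))  # rules echoed
})

test_that("noiseless natural winters bracket the effective adequacy threshold", {
  # the generator's logistic is centred on true_cr; the default rule
  # (FBP >= 95) is met at true_cr + log(15)/steepness, the effective
  # threshold whose containment is exact in the absence of noise
  for (seed in 1:5) {
    s <- simulate_winter(winter_config(seed = seed))
    start <- detect_start_date(s, 7.2)
    dates <- seq(as.Date(start) + 14, by = 14, length.out = 7)
    trts <- lapply(seq_along(dates), function(i)
      treatment(sprintf("n%d", i), "natural", start,
                as.POSIXct(paste(dates[i], "10:00:00"), tz = "UTC")))
    model <- chill_hours()
    acc <- vapply(trts, treatment_accumulation, numeric(1),
                  model = model, series = s, start = start)
    names(acc) <- sprintf("n%d", seq_along(dates))
    cfg <- morpho_sim_config(true_cr = 600, steepness = 0.1, seed = seed)
    cfg$indices$noise_sd <- 0
    morpho <- simulate_morphology(acc, cfg)
    fit <- estimate_cr(trts, morpho, model, series = s, start = start,
                       rank = FALSE)
    eff <- 600 + log((95 - 20) / (100 - 95)) / 0.1
    if (max(acc) >= eff) {
      expect_true(fit$bracket$lower < eff)
      expect_true(fit$bracket$upper >= eff)
    }
  }
})
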