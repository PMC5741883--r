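#' Configuration for a simulated winter temperature record
#'
#' The generator composes (i) an annual cosine with its minimum at
#' mid-January, (ii) a diurnal cosine with its minimum pre-dawn (05:00),
#' (iii) stationary AR(1) noise on the hourly grid, and (iv) a uniform
#' `warm_offset` emulating a warmer winter. Defaults are chosen to
#' resemble a subtropical east-China winter (mid-winter daily means a few
#' degrees above zero, chill-hour band reached in early December).
#'
#' @param start,end span of the record (dates); must cover at least 60
#'   days.
#' @param seasonal_mean annual-cosine value at the mid-January minimum,
#'   degrees C (default 4).
#' @param seasonal_amplitude annual-cosine amplitude, degrees C
#'   (default 10; summer sits `2 * amplitude` above the winter minimum).
#' @param diurnal_amplitude half-range of the day/night cycle, degrees C
#'   (default 4).
#' @param ar1_rho lag-1 autocorrelation of the hourly noise, in `[0, 1)`
#'   (default 0.7).
#' @param noise_sd stationary standard deviation of the noise, degrees C
#'   (default 1.5, `>= 0`).
#' @param warm_offset added uniformly to every reading, degrees C.
#' @param seed integer seed; the generator is a pure function of its
#'   configuration including the seed.
#' @param season_label label for the series.
#' @return list of class `winter_config`.
#' @export
winter_config <- function(start = "2012-11-01", end = "2013-03-15",
                          seasonal_mean = 4, seasonal_amplitude = 10,
                          diurnal_amplitude = 4, ar1_rho = 0.7,
                          noise_sd = 1.5, warm_offset = 0, seed = 1,
                          season_label = "simulated") {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end) ||
      as.numeric(end - start) < 60) {
    abort("winter span must cover at least 60 days", "budchill_config_error")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0", "budchill_config_error")
  if (ar1_rho < 0 || ar1_rho >= 1) {
    abort("ar1_rho must be in [0, 1)", "budchill_config_error")
  }
  structure(list(start = start, end = end, seasonal_mean = seasonal_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude, ar1_rho = ar1_rho,
                 noise_sd = noise_sd, warm_offset = warm_offset,
                 seed = seed, season_label = season_label),
            class = "winter_config")
}

mid_january <- function(start, end) {
  yr <- as.integer(format(end, "%Y"))
  cand <- as.Date(sprintf("%d-01-15", c(yr - 1L, yr, yr + 1L)))
  cand[which.min(abs(as.numeric(cand - (start + (end - start) / 2))))]
}

#' Simulate an hourly winter temperature series
#'
#' @param config a [winter_config()].
#' @return an [hourly_series()]; identical for identical configurations.
#' @examples
#' s <- simulate_winter(winter_config(noise_sd = 0, diurnal_amplitude = 0))
#' head(daily_means(s))
#' @export
simulate_winter <- function(config = winter_config()) {
  stopifnot(inherits(config, "winter_config"))
  ts <- seq(as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(config$end, "23:00:00"), tz = "UTC"),
            by = "hour")
  anchor <- as.POSIXct(paste(mid_january(config$start, config$end),
                             "00:00:00"), tz = "UTC")
  d <- as.numeric(difftime(ts, anchor, units = "days"))
  seasonal <- config$seasonal_mean +
    config$seasonal_amplitude * (1 - cos(2 * pi * d / 365.25))
  hour <- as.numeric(format(ts, "%H"))
  diurnal <- -config$diurnal_amplitude * cos(2 * pi * (hour - 5) / 24)
  noise <- if (config$noise_sd == 0) {
    numeric(length(ts))
  } else {
    with_seed(config$seed, {
      innov_sd <- config$noise_sd * sqrt(1 - config$ar1_rho^2)
      e <- numeric(length(ts))
      e[1L] <- stats::rnorm(1L, 0, config$noise_sd)
      z <- stats::rnorm(length(ts) - 1L, 0, innov_sd)
      for (i in seq_along(z)) e[i + 1L] <- config$ar1_rho * e[i] + z[i]
      e
    })
  }
  temp <- seasonal + diurnal + noise + config$warm_offset
  hourly_series(ts, pmin(pmax(temp, -30), 50),
                season_label = config$season_label)
}

#' Configuration for chill-dose-responsive morphology
#'
#' Each index responds to accumulated chill through a logistic centred on
#' the planted true chilling requirement `true_cr`:
#' `baseline + (saturation - baseline) * logistic(steepness * (chill -
#' true_cr))`. Lower-is-better indices simply have `saturation <
#' baseline`. Replicate noise is additive Gaussian on the index scale.
#'
#' @param true_cr planted chilling requirement, model units, > 0
#'   (default 600 CH).
#' @param steepness logistic slope per chill unit, > 0 (default 0.1: the
#'   transition from baseline to saturation spans roughly 100 CH,
#'   i.e. well under the weekly treatment spacing).
#' @param indices data frame with columns `index_code`, `baseline`,
#'   `saturation`, `noise_sd`; defaults cover FBP, BBP, NOF, ANS, APH and
#'   DEA with noise levels typical of 3-replicate morphology scoring
#'   (about 2 percentage points on budbreak percentages).
#' @param n_replicates replicates per treatment x index (default 3).
#' @param seed integer seed.
#' @return list of class `morpho_sim_config`.
#' @export
morpho_sim_config <- function(true_cr = 600, steepness = 0.1,
                              indices = default_morpho_indices(),
                              n_replicates = 3, seed = 1) {
  if (true_cr <= 0) abort("true_cr must be > 0", "budchill_config_error")
  if (steepness <= 0) abort("steepness must be > 0", "budchill_config_error")
  stopifnot(is.data.frame(indices),
            all(c("index_code", "baseline", "saturation", "noise_sd") %in%
                  names(indices)))
  structure(list(true_cr = true_cr, steepness = steepness,
                 indices = indices, n_replicates = as.integer(n_replicates),
                 seed = seed),
            class = "morpho_sim_config")
}

#' Default simulated morphology index set
#' @return data frame of index specifications (see [morpho_sim_config()]).
#' @export
default_morpho_indices <- function() {
  data.frame(
    index_code = c("FBP", "BBP", "NOF", "ANS", "APH", "DEA"),
    baseline   = c(20,    10,    0,     1,     25,    70),
    saturation = c(100,   90,    3,     4,     60,    12),
    noise_sd   = c(2,     3,     0.3,   0.3,   2,     2),
    stringsAsFactors = FALSE
  )
}

#' Simulate a chill-dose-responsive morphology table
#'
#' @param accumulations named numeric vector of chill totals per
#'   treatment id.
#' @param config a [morpho_sim_config()].
#' @return long-format morphology data frame (columns `treatment_id`,
#'   `index_code`, `replicate`, `value`) suitable for
#'   [adequacy_labels()] and [composite_rank()]. Percentages are clamped
#'   to `[0, 100]` and counts to `>= 0`.
#' @export
simulate_morphology <- function(accumulations, config = morpho_sim_config()) {
  stopifnot(inherits(config, "morpho_sim_config"))
  if (is.null(names(accumulations)) || anyNA(accumulations)) {
    abort("accumulations must be a complete named vector",
          "budchill_input_error")
  }
  idx <- config$indices
  grid <- expand.grid(treatment_id = names(accumulations),
                      index_code = idx$index_code,
                      replicate = seq_len(config$n_replicates),
                      stringsAsFactors = FALSE)
  j <- match(grid$index_code, idx$index_code)
  chill <- accumulations[grid$treatment_id]
  mu <- idx$baseline[j] + (idx$saturation[j] - idx$baseline[j]) *
    logistic(config$steepness * (chill - config$true_cr))
  noise <- with_seed(config$seed,
                     stats::rnorm(nrow(grid), 0, idx$noise_sd[j]))
  v <- mu + noise
  pct <- grid$index_code %in% c("FBP", "BBP")
  v[pct] <- pmin(pmax(v[pct], 0), 100)
  cnt <- grid$index_code %in% c("NOF", "ANS")
  v[cnt] <- pmax(v[cnt], 0)
  grid$value <- v
  grid
}

#' Configuration for paired-winter expression simulation
#'
#' Three gene classes: `cr_congruent` genes carry a Gaussian expression
#' bump centred on each winter's CR-fulfillment checkpoint (so the
#' planted between-winter lag equals the checkpoint difference);
#' `late_photoperiod` genes rise monotonically toward the last
#' checkpoint in both winters; `fluctuating` genes are pure noise.
#' Profile noise is additive with standard deviation `noise_sd` in units
#' of the profile's own spread (i.e. on the standardized scale); Ct noise
#' is on the cycle scale.
#'
#' @param n_genes total genes (default 12, split by `proportions`).
#' @param proportions named numeric proportions for classes
#'   `cr_congruent`, `late_photoperiod`, `fluctuating`; must sum to 1.
#' @param bump_width Gaussian bump width in checkpoints (default 1: the
#'   active period spans roughly two sampling dates).
#' @param noise_sd profile noise on the standardized scale (default 0.2).
#' @param ct_noise_sd technical qPCR noise in cycles (default 0.15).
#' @param n_checkpoints checkpoints per winter (default 6).
#' @param seed integer seed.
#' @return list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 12,
                                  proportions = c(cr_congruent = 1 / 3,
                                                  late_photoperiod = 1 / 3,
                                                  fluctuating = 1 / 3),
                                  bump_width = 1, noise_sd = 0.2,
                                  ct_noise_sd = 0.15, n_checkpoints = 6,
                                  seed = 1) {
  need <- c("cr_congruent", "late_photoperiod", "fluctuating")
  if (!all(need %in% names(proportions)) ||
      abs(sum(proportions) - 1) > 1e-8) {
    abort("proportions must cover the three classes and sum to 1",
          "budchill_config_error")
  }
  structure(list(n_genes = as.integer(n_genes),
                 proportions = proportions[need],
                 bump_width = bump_width, noise_sd = noise_sd,
                 ct_noise_sd = ct_noise_sd,
                 n_checkpoints = as.integer(n_checkpoints), seed = seed),
            class = "expression_sim_config")
}

#' Simulate paired-winter expression matrices with a planted lag
#'
#' @param config an [expression_sim_config()].
#' @param fulfillment_checkpoint_a,fulfillment_checkpoint_b index (1-based)
#'   of the CR-fulfillment checkpoint in winter a and winter b; the
#'   planted lag of `cr_congruent` genes is `b - a`.
#' @return list with `matrix_a`, `matrix_b` (FPKM [expression_matrix()]s),
#'   `qpcr_a`, `qpcr_b` (long-format Ct tables with a reference gene),
#'   `truth` (data frame `gene_id`, `class`), `planted_lag`.
#' @export
simulate_expression_pair <- function(config = expression_sim_config(),
                                     fulfillment_checkpoint_a = 4,
                                     fulfillment_checkpoint_b = 5) {
  stopifnot(inherits(config, "expression_sim_config"))
  ncp <- config$n_checkpoints
  for (cp in c(fulfillment_checkpoint_a, fulfillment_checkpoint_b)) {
    if (cp < 1 || cp > ncp) {
      abort("fulfillment checkpoint index outside profile",
            "budchill_input_error")
    }
  }
  n <- config$n_genes
  counts <- diff(round(cumsum(c(0, config$proportions)) * n))
  classes <- rep(names(config$proportions), counts)
  length(classes) <- n
  classes[is.na(classes)] <- "fluctuating"
  gene_ids <- sprintf("gene%03d", seq_len(n))
  t <- seq_len(ncp)
  base_profile <- function(class, center) {
    switch(class,
           cr_congruent = 5 + 50 * exp(-(t - center)^2 /
                                         (2 * config$bump_width^2)),
           late_photoperiod = 5 + 45 * (t - 1) / (ncp - 1),
           fluctuating = rep(20, ncp))
  }
  sim <- with_seed(config$seed, {
    make_matrix <- function(center) {
      rows <- lapply(seq_len(n), function(i) {
        base <- base_profile(classes[i], center)
        spread <- stats::sd(base)
        if (classes[i] == "fluctuating" || spread == 0) spread <- 10
        pmax(base + stats::rnorm(ncp, 0, config$noise_sd * spread), 0.01)
      })
      m <- do.call(rbind, rows)
      dimnames(m) <- list(gene_ids, sprintf("cp%d", t))
      m
    }
    ma <- make_matrix(fulfillment_checkpoint_a)
    mb <- make_matrix(fulfillment_checkpoint_b)
    list(ma = ma, mb = mb,
         qa = ct_table(ma, config$ct_noise_sd),
         qb = ct_table(mb, config$ct_noise_sd))
  })
  list(matrix_a = expression_matrix(sim$ma),
       matrix_b = expression_matrix(sim$mb),
       qpcr_a = sim$qa, qpcr_b = sim$qb,
       truth = data.frame(gene_id = gene_ids, class = classes,
                          stringsAsFactors = FALSE),
       planted_lag = fulfillment_checkpoint_b - fulfillment_checkpoint_a)
}

# long-format Ct table: target Ct = reference Ct - log2(relative abundance),
# 3 biological x 3 technical replicates, plus reference-gene rows
ct_table <- function(mat, ct_noise_sd, ref_ct = 20, scale_fpkm = 10) {
  genes <- rownames(mat)
  cps <- colnames(mat)
  rows <- list()
  k <- 1L
  for (cp in cps) {
    for (b in 1:3) {
      ref_mean <- ref_ct + stats::rnorm(1, 0, ct_noise_sd)
      rows[[k]] <- data.frame(
        gene_id = "reference", date = cp, biological = b,
        technical = 1:3,
        ct = ref_mean + stats::rnorm(3, 0, ct_noise_sd),
        is_reference = TRUE)
      k <- k + 1L
      for (g in genes) {
        target_mean <- ref_mean - log2(mat[g, cp] / scale_fpkm)
        rows[[k]] <- data.frame(
          gene_id = g, date = cp, biological = b, technical = 1:3,
          ct = target_mean + stats::rnorm(3, 0, ct_noise_sd),
          is_reference = FALSE)
        k <- k + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  out$ct <- pmin(pmax(out$ct, 1), 44)
  out
}
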