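#' Six-checkpoint expression profile
#'
#' One gene's standardized expression over the dated sampling checkpoints
#' of a winter (default 6 points, Nov 26 through Feb 25 pattern).
#'
#' @param values numeric vector of (standardized) expression values, one
#'   per checkpoint, finite.
#' @param gene_id,winter labels.
#' @param n_checkpoints expected length (default 6).
#' @return numeric vector of class `checkpoint_profile`.
#' @export
checkpoint_profile <- function(values, gene_id = "", winter = "",
                               n_checkpoints = 6) {
  values <- as.numeric(values)
  if (length(values) != n_checkpoints) {
    abort(sprintf("profile must have %d checkpoints, got %d",
                  n_checkpoints, length(values)),
          "budchill_input_error")
  }
  if (any(!is.finite(values))) {
    abort("profile values must be finite", "budchill_input_error")
  }
  structure(values, gene_id = gene_id, winter = winter,
            class = "checkpoint_profile")
}

#' Best lag between two checkpoint profiles
#'
#' Slides profile `b` against profile `a` by whole checkpoint steps and
#' computes the Pearson correlation over the overlapping checkpoints at
#' each lag in `[-max_lag, +max_lag]`. A positive lag means `b` is
#' delayed relative to `a`. Ties prefer the smaller `|lag|`, then the
#' negative lag. Lags whose overlap contains a constant profile are
#' skipped; six points is very short for lag analysis, so at least three
#' overlapping checkpoints are always required.
#'
#' @param a,b numeric profiles of equal length (see
#'   [checkpoint_profile()]; plain numeric vectors accepted).
#' @param max_lag largest lag searched, `<= length - 3` (default 2).
#' @return object of class `lag_result`: `best_lag`, `r_zero`
#'   (correlation at lag 0, `NA` if skipped), `r_best`, `n_overlap` (at
#'   the best lag), `r_by_lag` (named vector over all lags).
#' @export
best_lag <- function(a, b, max_lag = 2) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  n <- length(a)
  if (length(b) != n) {
    abort("profiles must have the same length", "budchill_input_error")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("profile values must be finite", "budchill_input_error")
  }
  max_lag <- as.integer(max_lag)
  if (max_lag < 0 || max_lag > n - 3L) {
    abort(sprintf("max_lag must be in [0, %d] for length-%d profiles",
                  n - 3L, n),
          "budchill_config_error")
  }
  lags <- seq.int(-max_lag, max_lag)
  r <- vapply(lags, function(L) {
    if (L >= 0) {
      av <- a[seq_len(n - L)]
      bv <- b[seq_len(n - L) + L]
    } else {
      av <- a[seq_len(n + L) - L]
      bv <- b[seq_len(n + L)]
    }
    if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
    stats::cor(av, bv)
  }, numeric(1))
  names(r) <- as.character(lags)
  if (all(is.na(r))) {
    abort("constant profile at every lag; lag undefined",
          "budchill_degenerate_error")
  }
  # argmax with tie-break: larger r, then smaller |lag|, then negative lag
  ord <- order(-r, abs(lags), lags, na.last = TRUE)
  best <- ord[1L]
  structure(list(best_lag = lags[best],
                 r_zero = unname(r[as.character(0)]),
                 r_best = unname(r[best]),
                 n_overlap = n - abs(lags[best]),
                 r_by_lag = r),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("Best lag %+d checkpoint(s): r = %.3f (r at lag 0: %s; overlap %d)\n",
              x$best_lag, x$r_best,
              if (is.na(x$r_zero)) "NA" else sprintf("%.3f", x$r_zero),
              x$n_overlap))
  invisible(x)
}

#' Classify the between-winter congruence of a profile pair
#'
#' Three mutually exclusive types: `shifted_similar` (the profiles agree
#' strongly after a non-zero shift that clearly improves on the unshifted
#' agreement), `partially_similar` (substantial agreement with or without
#' shift), `dissimilar` (hardly any similarity). The thresholds are
#' declared configuration and echoed in reports.
#'
#' @param result a [best_lag()] result.
#' @param r_high correlation required at the best lag for
#'   `shifted_similar` (default 0.8).
#' @param r_mid correlation floor for `partially_similar` (default 0.5).
#' @param gain minimum improvement `r_best - r_zero` for a shift to count
#'   (default 0.2).
#' @return character scalar, one of `"shifted_similar"`,
#'   `"partially_similar"`, `"dissimilar"`; attribute `thresholds`.
#' @export
classify_congruence <- function(result, r_high = 0.8, r_mid = 0.5,
                                gain = 0.2) {
  stopifnot(inherits(result, "lag_result"))
  r0 <- if (is.na(result$r_zero)) -Inf else result$r_zero
  type <- if (abs(result$best_lag) >= 1 && result$r_best >= r_high &&
              (result$r_best - r0) >= gain) {
    "shifted_similar"
  } else if (max(r0, result$r_best) >= r_mid) {
    "partially_similar"
  } else {
    "dissimilar"
  }
  structure(type, thresholds = c(r_high = r_high, r_mid = r_mid,
                                 gain = gain))
}

#' Does an expression shift match the CR-fulfillment delay?
#'
#' Flags a gene as CR-congruent when its between-winter profile shift is
#' of the `shifted_similar` type and the shift, converted to days via the
#' checkpoint spacing, matches the CR-fulfillment delay to within one
#' checkpoint interval. A shift much longer than the delay (e.g. more
#' than a month against a 2-week delay) is not congruent.
#'
#' @param result a [best_lag()] result.
#' @param fulfillment_delay_days CR-fulfillment delay in days (winter b
#'   minus winter a), or `NA` if undefined.
#' @param checkpoint_spacing_days representative (median) spacing of the
#'   sampling calendar in days, > 0.
#' @param ... thresholds passed to [classify_congruence()].
#' @return object of class `congruence_report`: list with `congruent`
#'   (logical, `NA` when not evaluable), `type`, `shift_days`,
#'   `delay_days`, `spacing_days`.
#' @export
congruence_with_fulfillment <- function(result, fulfillment_delay_days,
                                        checkpoint_spacing_days, ...) {
  stopifnot(inherits(result, "lag_result"))
  if (!is.numeric(checkpoint_spacing_days) ||
      checkpoint_spacing_days <= 0) {
    abort("checkpoint_spacing_days must be > 0", "budchill_config_error")
  }
  type <- classify_congruence(result, ...)
  shift_days <- result$best_lag * checkpoint_spacing_days
  congruent <- if (is.na(fulfillment_delay_days)) {
    NA
  } else {
    type == "shifted_similar" &&
      abs(shift_days - fulfillment_delay_days) <= checkpoint_spacing_days
  }
  structure(list(congruent = congruent, type = as.character(type),
                 shift_days = shift_days,
                 delay_days = fulfillment_delay_days,
                 spacing_days = checkpoint_spacing_days,
                 thresholds = attr(type, "thresholds")),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("Congruence: type %s, shift %+g d vs delay %s d -> %s\n",
              x$type, x$shift_days,
              if (is.na(x$delay_days)) "NA" else sprintf("%g", x$delay_days),
              if (is.na(x$congruent)) "not evaluable"
              else if (x$congruent) "CR-congruent" else "not congruent"))
  invisible(x)
}

#' Congruence analysis of two winters' expression matrices
#'
#' Standardizes both matrices ([heatmap_normalize()]), computes the best
#' lag per shared gene and flags CR-congruence against the supplied
#' fulfillment delay.
#'
#' @param mat_a,mat_b expression matrices (same genes, same number of
#'   checkpoints; winter a and winter b).
#' @param fulfillment_delay_days delay in days (`NA` allowed).
#' @param checkpoint_spacing_days sampling-calendar spacing in days.
#' @param max_lag see [best_lag()].
#' @param ... thresholds passed to [classify_congruence()].
#' @return data frame with one row per gene: `gene_id`, `best_lag`,
#'   `r_zero`, `r_best`, `type`, `congruent`. Genes degenerate at every
#'   lag get `NA` lag and type `"dissimilar"`.
#' @export
congruence_screen <- function(mat_a, mat_b, fulfillment_delay_days,
                              checkpoint_spacing_days, max_lag = 2, ...) {
  genes <- intersect(rownames(mat_a), rownames(mat_b))
  if (length(genes) == 0L) {
    abort("no shared genes between winters", "budchill_input_error")
  }
  za <- heatmap_normalize(mat_a[genes, , drop = FALSE])
  zb <- heatmap_normalize(mat_b[genes, , drop = FALSE])
  rows <- lapply(genes, function(g) {
    res <- tryCatch(best_lag(za[g, ], zb[g, ], max_lag = max_lag),
                    budchill_degenerate_error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(gene_id = g, best_lag = NA_integer_,
                        r_zero = NA_real_, r_best = NA_real_,
                        type = "dissimilar", congruent = FALSE))
    }
    rep <- congruence_with_fulfillment(res, fulfillment_delay_days,
                                       checkpoint_spacing_days, ...)
    data.frame(gene_id = g, best_lag = res$best_lag, r_zero = res$r_zero,
               r_best = res$r_best, type = rep$type,
               congruent = rep$congruent)
  })
  do.call(rbind, rows)
}
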