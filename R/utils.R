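#' @keywords internal
"_PACKAGE"

# error helper: all package errors subclass "budchill_error"
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "budchill_error", "error")))
}

#' Round half away from zero
#'
#' Presentation-layer rounding used for chill totals: internal accumulation
#' keeps full precision, printed totals use two decimals with halves rounded
#' up (so 147.672 prints as 147.67 and 443.016 as 443.02).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# format a chill total for reports (2 d.p., half-up)
format_chill <- function(x) sprintf("%.2f", round_half_up(x, 2))

# evaluate `code` with a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators are pure functions of their seed
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("seed must be a single finite number", "budchill_config_error")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# standard logistic
logistic <- function(x) 1 / (1 + exp(-x))

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("%s must be a single finite number", name),
          "budchill_input_error")
  }
  invisible(x)
}
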