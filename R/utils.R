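#' Decimal-faithful rounding helpers
#'
#' `round_dp()` rounds to `digits` decimal places with the round-half-to-even
#' rule applied to the *decimal* value, not its binary representation: the
#' value is first snapped to 12 significant decimal digits so that a quantity
#' that is exactly `x.x5` in decimal arithmetic (e.g. 58.3/22 = 2.65) rounds
#' to even (2.6) rather than being tipped by floating-point noise.
#' `format_sig()` formats at 3 significant figures, the display convention
#' used throughout reports.
#'
#' Internal computation in this package is always full precision; these
#' helpers are applied only when a number is displayed or a printed-style
#' value is requested.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (`round_dp`) or significant figures
#'   (`format_sig`).
#' @return `round_dp()` a numeric vector; `format_sig()` a character vector.
#' @examples
#' round_dp(58.3 / 22, 1) # 2.65 -> 2.6 (half to even)
#' format_sig(2 * 2.66 * 23.1) # "123"
#' @export
round_dp <- function(x, digits = 1) {
  round(signif(x, 12), digits)
}

#' @rdname round_dp
#' @export
format_sig <- function(x, digits = 3) {
  format(signif(x, digits), trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

# Extract the numeric measurement vector from whatever the user passed:
# an observation_set / data frame with a `value` column, or a bare numeric.
obs_values <- function(data) {
  if (is.data.frame(data)) {
    if (!"value" %in% names(data)) {
      stop("data frame input must have a `value` column", call. = FALSE)
    }
    v <- data$value
  } else if (is.numeric(data)) {
    v <- as.numeric(data)
  } else {
    stop("input must be numeric or a data frame with a `value` column",
      call. = FALSE
    )
  }
  if (anyNA(v) || any(!is.finite(v))) {
    stop("missing value: all measurements must be finite", call. = FALSE)
  }
  v
}

obs_labels <- function(data) {
  if (is.data.frame(data) && "label" %in% names(data)) {
    as.character(data$label)
  } else {
    as.character(seq_along(obs_values(data)))
  }
}

check_n <- function(x, min_n = 2L, what = "observations") {
  if (length(x) < min_n) {
    stop(sprintf("insufficient data: need at least %d %s", min_n, what),
      call. = FALSE
    )
  }
  invisible(x)
}

# Strict-inequality exceedance: points ON a limit are not flagged.
which_outside <- function(values, lower, upper) {
  which(values < lower | values > upper)
}
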