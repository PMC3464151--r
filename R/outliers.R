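#' Lower and upper quartiles
#'
#' Default convention is Tukey hinges -- the medians of the lower and upper
#' halves of the sorted data, halves including the overall median when n is
#' odd (computed via [stats::fivenum()]).  An interpolation-based
#' alternative ([stats::quantile()] type 7) is selectable; reports record
#' which convention produced their numbers, since quartile conventions can
#' move the fences.
#'
#' @inheritParams moving_ranges
#' @param method `"hinges"` (Tukey hinges, default) or `"interpolation"`
#'   (type-7 quantiles).
#' @return Named numeric vector `c(q1 = ..., q3 = ...)`.
#' @examples
#' quartiles(c(1, 2, 3, 4)) # hinges 1.5 and 3.5
#' quartiles(1:5) # 2 and 4: halves include the median
#' @export
quartiles <- function(data, method = c("hinges", "interpolation")) {
  method <- match.arg(method)
  x <- obs_values(data)
  check_n(x)
  q <- if (method == "hinges") {
    stats::fivenum(x)[c(2, 4)]
  } else {
    unname(stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE))
  }
  c(q1 = q[1], q3 = q[2])
}

#' Tukey's fences
#'
#' Order-free outlier bounds at `Q1 - k*(Q3 - Q1)` and `Q3 + k*(Q3 - Q1)`;
#' k = 1.5 gives the inner fences, k = 3 the outer fences.  Because the
#' fences depend only on the quartiles, they are invariant under any
#' permutation of the data -- the recommended special-cause screen for data
#' without an inherent ordering (appropriate in particular for skewed data,
#' where symmetric sigma limits mislead).
#'
#' @inheritParams quartiles
#' @param k Fence multiplier (>= 0).
#' @param quartile_method Passed to [quartiles()].
#' @return A one-row tibble of class `tukey_fences` with columns `q1`, `q3`,
#'   `iqr`, `k`, `lower`, `upper`, `kind` (`"inner"`, `"outer"` or
#'   `"custom"`), `quartile_method`.
#' @examples
#' tukey_fences(c(1, 2, 3, 4), k = 1.5) # fences -1.5 and 6.5
#' @export
tukey_fences <- function(data, k = 1.5,
                         quartile_method = c("hinges", "interpolation")) {
  quartile_method <- match.arg(quartile_method)
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  q <- quartiles(data, method = quartile_method)
  iqr <- q[["q3"]] - q[["q1"]]
  out <- tibble::tibble(
    q1 = q[["q1"]], q3 = q[["q3"]], iqr = iqr, k = k,
    lower = q[["q1"]] - k * iqr,
    upper = q[["q3"]] + k * iqr,
    kind = if (k == 1.5) "inner" else if (k == 3) "outer" else "custom",
    quartile_method = quartile_method
  )
  class(out) <- c("tukey_fences", class(out))
  out
}

#' Average-and-standard-deviation (sigma) limits
#'
#' The 3-sigma rule as a chart: centre = mean, limits = mean +/- `n_sigma`
#' sample standard deviations (n-1 denominator).  Like the fences, and
#' unlike XmR limits, these depend only on the multiset of values, never on
#' their order.
#'
#' @inheritParams moving_ranges
#' @param n_sigma Number of standard deviations (default 3).
#' @return A one-row control-limits tibble with `chart_kind = "average_sd"`.
#' @examples
#' sigma_limits(c(0, 10)) # mean 5, sd 10/sqrt(2)
#' @export
sigma_limits <- function(data, n_sigma = 3) {
  x <- obs_values(data)
  check_n(x)
  m <- mean(x)
  s <- stats::sd(x)
  control_limits_row("average_sd", m, m - n_sigma * s, m + n_sigma * s)
}

#' Flag points outside order-free bounds
#'
#' Indices of values strictly outside `[lower, upper]` of the supplied
#' fences or limits.  For the same data, the outer fences always flag a
#' subset of what the inner fences flag.
#'
#' @inheritParams moving_ranges
#' @param bounds A one-row tibble with `lower` and `upper` columns
#'   ([tukey_fences()], [sigma_limits()], or a row of [xmr_limits()]).
#' @return A tibble with columns `index`, `label`, `value`.
#' @examples
#' flag_outliers(c(1, 2, 3, 4, 100), tukey_fences(c(1, 2, 3, 4, 100)))
#' @export
flag_outliers <- function(data, bounds) {
  detect_signals(data, bounds)
}
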