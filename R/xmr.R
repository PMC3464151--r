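# Shewhart constants for the XmR chart: E2 = 3/d2 with d2 = 1.128 for
# subgroups of size 2, conventionally quoted as 2.66; D4 = 3.267 bounds the
# moving-range chart.  Configuration values, not inline literals.
.xmr_constants <- list(E2 = 2.66, D4 = 3.267)

#' Moving ranges and the average moving range
#'
#' For an *ordered* series y_1, ..., y_n the moving ranges are the absolute
#' successive differences |y_(j+1) - y_j|, j = 1..n-1, and the average
#' moving range (mR-bar) is their arithmetic mean -- the dispersion estimate
#' on which XmR control limits are built.  Because each term depends on which
#' values are adjacent, mR-bar depends on the ordering of the data (it is
#' invariant only under reversal).
#'
#' @param data An [observation_set()], data frame with a `value` column, or
#'   numeric vector, in the ordering to be analysed.  Row/element order is
#'   taken as the series order.
#' @return `moving_ranges()`: a list of class `moving_range_summary` with
#'   elements `moving_ranges` (length n-1), `mr_bar`, `n`.
#'   `mr_bar()`: the average moving range as a bare number.
#' @examples
#' moving_ranges(c(0, 3, 1)) # ranges 3, 2; mR-bar 2.5
#' mr_bar(c(0, 1, 3)) == mr_bar(c(3, 1, 0)) # reversal invariance
#' @export
moving_ranges <- function(data) {
  y <- obs_values(data)
  check_n(y)
  mr <- abs(diff(y))
  structure(
    list(moving_ranges = mr, mr_bar = mean(mr), n = length(y)),
    class = "moving_range_summary"
  )
}

#' @rdname moving_ranges
#' @export
mr_bar <- function(data) {
  y <- obs_values(data)
  check_n(y)
  mean(abs(diff(y)))
}

#' @export
print.moving_range_summary <- function(x, ...) {
  cat("Moving ranges (n = ", x$n, "): ",
    paste(format_sig(x$moving_ranges), collapse = ", "), "\n",
    "Average moving range: ", format_sig(x$mr_bar), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.moving_range_summary <- function(x, ...) {
  tibble::tibble(index = seq_along(x$moving_ranges), moving_range = x$moving_ranges)
}

# One row of the common control-limits schema shared by every chart type.
control_limits_row <- function(chart_kind, center, lower, upper) {
  tibble::tibble(
    chart_kind = chart_kind,
    center = center,
    lower = lower,
    upper = upper,
    width = upper - lower,
    lower_clipped_at_zero = lower < 0
  )
}

#' XmR control limits
#'
#' Individuals chart: centre = mean of the values, limits = mean +/-
#' `constant` x mR-bar (default `constant` 2.66, the E2 = 3/d2 convention).
#' Moving-range chart: centre = mR-bar, lower limit 0, upper = `d4` x mR-bar
#' (D4 = 3.267).  `mr_bar` may be overridden to inject, e.g., the extremal
#' mR-bar values, which is how the ambiguity of the limits under reordering
#' is quantified.  The raw (pre-clipping) lower limit is always retained;
#' `lower_clipped_at_zero` records when the interpretive lower bound for
#' bounded data (such as percentages) would be 0 instead.
#'
#' @inheritParams moving_ranges
#' @param mr_bar Optional non-negative override for the average moving range.
#' @param constant Individuals-chart multiplier (default 2.66).
#' @param d4 Moving-range-chart upper multiplier (default 3.267).
#' @return A tibble with one row per chart (`x_individuals`, `moving_range`)
#'   and columns `chart_kind`, `center`, `lower`, `upper`, `width`,
#'   `lower_clipped_at_zero`.
#' @examples
#' xmr_limits_from_stats(33.7, 2.6) # limits 26.8 and 40.6, width 13.8
#' @export
xmr_limits <- function(data, mr_bar = NULL,
                       constant = .xmr_constants$E2, d4 = .xmr_constants$D4) {
  y <- obs_values(data)
  check_n(y)
  mrb <- if (is.null(mr_bar)) mean(abs(diff(y))) else mr_bar
  if (mrb < 0) stop("mr_bar override must be non-negative", call. = FALSE)
  xmr_limits_from_stats(mean(y), mrb, constant = constant, d4 = d4)
}

#' @rdname xmr_limits
#' @param center Process centre (mean of the individual values).
#' @export
xmr_limits_from_stats <- function(center, mr_bar,
                                  constant = .xmr_constants$E2,
                                  d4 = .xmr_constants$D4) {
  if (mr_bar < 0) stop("mr_bar must be non-negative", call. = FALSE)
  dplyr::bind_rows(
    control_limits_row(
      "x_individuals", center,
      center - constant * mr_bar, center + constant * mr_bar
    ),
    control_limits_row("moving_range", mr_bar, 0, d4 * mr_bar)
  )
}

#' Points beyond control limits
#'
#' Rule-1 signal detection: indices of values strictly outside
#' `[lower, upper]` of the supplied limits (the raw, pre-clipping bounds).
#' Points exactly on a limit are not flagged.  Run rules and zone rules are
#' deliberately out of scope.
#'
#' @inheritParams moving_ranges
#' @param limits A one-row limits tibble (e.g. a row of [xmr_limits()],
#'   [sigma_limits()] or [tukey_fences()]).  If the two-row [xmr_limits()]
#'   output is given, the individuals-chart row is used.
#' @return A tibble with columns `index`, `label`, `value` of flagged points
#'   (zero rows when none).
#' @export
detect_signals <- function(data, limits) {
  y <- obs_values(data)
  lab <- obs_labels(data)
  lim <- limits
  if ("chart_kind" %in% names(lim) && nrow(lim) > 1) {
    lim <- lim[lim$chart_kind == "x_individuals", , drop = FALSE]
  }
  if (nrow(lim) != 1) stop("`limits` must resolve to one row", call. = FALSE)
  idx <- which_outside(y, lim$lower, lim$upper)
  tibble::tibble(index = idx, label = lab[idx], value = y[idx])
}
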