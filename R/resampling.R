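#' Resample the average moving range over random orderings
#'
#' Draws `n_resamples` independent uniformly random orderings of the data
#' (each a complete permutation: every datum appears exactly once per
#' ordering; orderings themselves are drawn with replacement from the
#' population of orderings) and computes the average moving range of each.
#' The empirical distribution shows how much the XmR dispersion estimate --
#' and hence the control limits -- moves under arbitrary reordering.
#' Shuffling uses R's Fisher-Yates `sample()` under the Mersenne-Twister
#' generator; results are bit-for-bit reproducible from `seed`.
#'
#' @inheritParams moving_ranges
#' @param n_resamples Number of random orderings (default 16383).
#' @param seed Integer seed; the sole source of randomness.
#' @return An object of class `mr_resample`: list with `values`, `seed`,
#'   `n_resamples`, `mr_values`.  Has [tidy()], [glance()], [autoplot()]
#'   methods.
#' @examples
#' rs <- sample_orderings(c(0, 1, 2, 4), n_resamples = 200, seed = 7)
#' range(rs$mr_values)
#' @export
sample_orderings <- function(data, n_resamples = 16383, seed = 1L) {
  x <- obs_values(data)
  check_n(x)
  if (n_resamples < 1) stop("n_resamples must be at least 1", call. = FALSE)
  mr_values <- withr::with_seed(seed, vapply(
    seq_len(n_resamples),
    function(i) mean(abs(diff(sample(x)))),
    numeric(1)
  ))
  structure(
    list(
      values = x, seed = as.integer(seed),
      n_resamples = as.integer(n_resamples), mr_values = mr_values
    ),
    class = "mr_resample"
  )
}

#' Summary statistics of a resampled mR-bar distribution
#'
#' Mean, standard error, median, standard deviation (n-1 denominator),
#' minimum, maximum, range, count, and a central interval at the requested
#' coverage.  Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7) -- stated because percentile conventions
#' differ.  A single-element distribution has its standard deviation
#' reported as 0 with a warning rather than an error, so pipelines keep
#' running on degenerate inputs while flagging them.
#'
#' @param dist An `mr_resample` object (or numeric vector of mR-bar values).
#' @param coverage Central coverage for the interval, in (0, 1); default
#'   0.95.
#' @return A one-row tibble with columns `mean`, `standard_error`, `median`,
#'   `standard_deviation`, `minimum`, `maximum`, `range`, `count`,
#'   `coverage`, `interval_lower`, `interval_upper`.
#' @examples
#' summarize_distribution(sample_orderings(c(0, 1, 3), 100, seed = 1))
#' @export
summarize_distribution <- function(dist, coverage = 0.95) {
  v <- if (inherits(dist, "mr_resample")) dist$mr_values else as.numeric(dist)
  if (length(v) == 0) stop("empty distribution", call. = FALSE)
  if (coverage <= 0 || coverage >= 1) {
    stop("coverage must lie in (0, 1)", call. = FALSE)
  }
  if (length(v) == 1) {
    warning("single-element distribution: standard deviation reported as 0")
    s <- 0
  } else {
    s <- stats::sd(v)
  }
  a <- (1 - coverage) / 2
  ci <- unname(stats::quantile(v, c(a, 1 - a), type = 7, names = FALSE))
  tibble::tibble(
    mean = mean(v),
    standard_error = s / sqrt(length(v)),
    median = stats::median(v),
    standard_deviation = s,
    minimum = min(v),
    maximum = max(v),
    range = max(v) - min(v),
    count = length(v),
    coverage = coverage,
    interval_lower = ci[1],
    interval_upper = ci[2]
  )
}

#' Histogram bins of a resampled distribution
#'
#' Equal-width bins spanning `[min, max]` of the values; bins are
#' right-open except the last, which is closed, so counts always sum to the
#' number of values.  Degenerate all-equal input yields a single bin.
#'
#' @inheritParams summarize_distribution
#' @param n_bins Number of bins (>= 1).
#' @return A tibble with columns `bin_lower`, `bin_upper`, `count`.
#' @export
histogram_bins <- function(dist, n_bins = 30) {
  v <- if (inherits(dist, "mr_resample")) dist$mr_values else as.numeric(dist)
  if (length(v) == 0) stop("empty distribution", call. = FALSE)
  if (n_bins < 1) stop("n_bins must be at least 1", call. = FALSE)
  lo <- min(v)
  hi <- max(v)
  if (lo == hi) {
    return(tibble::tibble(bin_lower = lo, bin_upper = hi, count = length(v)))
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  idx <- pmin(findInterval(v, breaks), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  tibble::tibble(
    bin_lower = breaks[-length(breaks)],
    bin_upper = breaks[-1],
    count = counts
  )
}

#' @export
print.mr_resample <- function(x, ...) {
  s <- summarize_distribution(x)
  cat(
    "Resampled average moving ranges: ", x$n_resamples,
    " orderings of n = ", length(x$values), " values (seed ", x$seed, ")\n",
    "  mean ", format_sig(s$mean), ", sd ", format_sig(s$standard_deviation),
    ", min ", format_sig(s$minimum), ", max ", format_sig(s$maximum), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mr_resample <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$mr_values), mr_bar = x$mr_values)
}

#' @exportS3Method generics::glance
glance.mr_resample <- function(x, coverage = 0.95, ...) {
  tibble::tibble(
    seed = x$seed, n = length(x$values),
    summarize_distribution(x, coverage = coverage)
  )
}

#' Histogram of the resampled mR-bar distribution
#'
#' ggplot2 histogram of the sampled average moving ranges with dashed lines
#' at the closed-form extrema of the data, showing how much of the
#' attainable range the sampled orderings cover.
#'
#' @param object An `mr_resample` object.
#' @param n_bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_resample <- function(object, n_bins = 30, ...) {
  ext <- mr_extrema(object$values)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mr_bar)) +
    ggplot2::geom_histogram(bins = n_bins, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(
      xintercept = c(ext$mr_bar_min, ext$mr_bar_max),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "average moving range",
      y = "orderings",
      title = "Average moving range over random orderings",
      subtitle = "dashed lines: attainable minimum and maximum"
    ) +
    ggplot2::theme_minimal()
}
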