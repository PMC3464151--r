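# Minimal exact big-integer product: little-endian base-1e9 digit vector
# held in doubles (every intermediate stays far below 2^53).  Used only for
# exact factorials, where doubles lose exactness past 22!.
big_product <- function(ks) {
  base <- 1e9
  d <- 1
  for (k in ks) {
    d <- d * k
    carry <- 0
    for (i in seq_along(d)) {
      v <- d[i] + carry
      d[i] <- v %% base
      carry <- v %/% base
    }
    while (carry > 0) {
      d <- c(d, carry %% base)
      carry <- carry %/% base
    }
  }
  d
}

big_to_string <- function(d) {
  d <- rev(d)
  paste0(
    format(d[1], scientific = FALSE),
    paste(sprintf("%09.0f", d[-1]), collapse = "")
  )
}

#' Number of orderings of a data set
#'
#' Exact n! (total orderings) and n!/2 (upper bound on distinct average
#' moving ranges, since the statistic is reversal-invariant), computed in
#' exact integer arithmetic -- never via floating-point factorials, which
#' lose exactness beyond 22!.  n!/2 is computed as the product 3 * 4 * ... *
#' n.
#'
#' @param n Number of observations (>= 2).
#' @return A list with `total` and `distinct_mr_upper_bound` as exact
#'   decimal strings, and `total_approx`, `distinct_approx` as doubles.
#' @examples
#' orderings_count(3)$total # "6"
#' orderings_count(23)$total # 23!, about 2.59e22
#' @export
orderings_count <- function(n) {
  if (n < 2) stop("insufficient data: need n >= 2", call. = FALSE)
  n <- as.integer(n)
  total <- big_product(seq_len(n))
  distinct <- if (n == 2L) 1 else big_product(3:n)
  list(
    total = big_to_string(total),
    distinct_mr_upper_bound = big_to_string(distinct),
    total_approx = exp(lfactorial(n)),
    distinct_approx = exp(lfactorial(n)) / 2
  )
}

#' Ambiguity report for XmR analysis of a data set
#'
#' Runs the full order-dependence argument as one computation: a summary of
#' the data; the closed-form extrema of the average moving range; the
#' individuals-chart limits and widths obtained from each extreme; the
#' absolute difference in limit width effected purely by reordering, and
#' that difference as a multiple of the data range; the exact count of
#' orderings; the number of points flagged under five schemes
#' (XmR limits at mR-bar_min, XmR limits at mR-bar_max, inner fences, outer
#' fences, 3-sigma); an optional resampled mR-bar distribution; a skewness
#' advisory (mean > median suggests Tukey's fences over sigma limits); and
#' a chart recommendation -- the XmR chart for data with an inherent order,
#' an order-free outlier method otherwise.
#'
#' @param data An [observation_set()]; its `has_inherent_order` flag drives
#'   the recommendation.
#' @param quartile_method Quartile convention for the fences.
#' @param limit_constant Individuals-chart multiplier (default 2.66).
#' @param resamples Optional number of random orderings to sample.
#' @param seed Seed for the optional resampling.
#' @param coverage Central-interval coverage for the resampling summary.
#' @return An object of class `ambiguity_report` (a list; see Details),
#'   with print, [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' obs <- generate_compliance_data(n = 23, seed = 42)
#' rep <- build_report(obs)
#' rep$width_difference
#' @export
build_report <- function(data, quartile_method = c("hinges", "interpolation"),
                         limit_constant = .xmr_constants$E2,
                         resamples = NULL, seed = 1L, coverage = 0.95) {
  quartile_method <- match.arg(quartile_method)
  x <- obs_values(data)
  check_n(x)
  n <- length(x)

  data_summary <- tibble::tibble(
    mean = mean(x), median = stats::median(x), sd = stats::sd(x),
    range = max(x) - min(x), min = min(x), max = max(x), count = n
  )

  ext <- mr_extrema(x)
  lim_min <- xmr_limits(x, mr_bar = ext$mr_bar_min, constant = limit_constant)[1, ]
  lim_max <- xmr_limits(x, mr_bar = ext$mr_bar_max, constant = limit_constant)[1, ]
  width_min <- lim_min$width
  width_max <- lim_max$width
  width_difference <- width_max - width_min
  data_range <- max(x) - min(x)
  width_over_range <- if (data_range > 0) width_difference / data_range else NA_real_

  inner <- tukey_fences(x, k = 1.5, quartile_method = quartile_method)
  outer <- tukey_fences(x, k = 3, quartile_method = quartile_method)
  sig3 <- sigma_limits(x, n_sigma = 3)

  flagged_counts <- tibble::tibble(
    scheme = c(
      "xmr_min_limits", "xmr_max_limits", "inner_fences",
      "outer_fences", "three_sigma"
    ),
    flagged = c(
      nrow(detect_signals(x, lim_min)),
      nrow(detect_signals(x, lim_max)),
      nrow(flag_outliers(x, inner)),
      nrow(flag_outliers(x, outer)),
      nrow(flag_outliers(x, sig3))
    )
  )

  resample <- NULL
  if (!is.null(resamples)) {
    resample <- sample_orderings(x, n_resamples = resamples, seed = seed)
  }

  counts <- orderings_count(n)
  structure(
    list(
      n = n,
      unit_label = unit_label(data),
      has_inherent_order = has_inherent_order(data),
      data_summary = data_summary,
      extremal = ext,
      limits_min = lim_min,
      limits_max = lim_max,
      fences_inner = inner,
      fences_outer = outer,
      sigma = sig3,
      width_min = width_min,
      width_max = width_max,
      width_difference = width_difference,
      width_difference_over_range = width_over_range,
      orderings_total = counts$total,
      orderings_distinct_upper_bound = counts$distinct_mr_upper_bound,
      flagged_counts = flagged_counts,
      resample = resample,
      skew_advisory = data_summary$mean > data_summary$median,
      recommendation = if (has_inherent_order(data)) {
        "use_xmr"
      } else {
        "use_outlier_methods"
      },
      config = list(
        limit_constant = limit_constant,
        quartile_method = quartile_method,
        seed = if (is.null(resamples)) NA_integer_ else as.integer(seed),
        coverage = coverage
      )
    ),
    class = "ambiguity_report"
  )
}

#' @export
print.ambiguity_report <- function(x, ...) {
  s <- x$data_summary
  cat("Ordering-ambiguity report (n = ", x$n, ")\n", sep = "")
  cat(
    "  data: mean ", format_sig(s$mean), ", median ", format_sig(s$median),
    ", sd ", format_sig(s$sd), ", range ", format_sig(s$range), "\n",
    sep = ""
  )
  cat(
    "  mR-bar attainable: ", format_sig(x$extremal$mr_bar_min), " to ",
    format_sig(x$extremal$mr_bar_max), "\n",
    sep = ""
  )
  cat(
    "  limit width: ", format_sig(x$width_min), " to ",
    format_sig(x$width_max),
    " (difference ", format_sig(x$width_difference),
    if (!is.na(x$width_difference_over_range)) {
      paste0(
        ", ", format_sig(x$width_difference_over_range),
        "x the data range"
      )
    } else {
      ""
    }, ")\n",
    sep = ""
  )
  cat("  orderings: ", x$orderings_total, " (n!)\n", sep = "")
  cat("  flagged points by scheme:\n")
  for (i in seq_len(nrow(x$flagged_counts))) {
    cat(
      "    ", format(x$flagged_counts$scheme[i], width = 16), " ",
      x$flagged_counts$flagged[i], "\n",
      sep = ""
    )
  }
  cat("  recommendation: ", x$recommendation, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ambiguity_report <- function(x, ...) {
  tibble::tibble(
    statistic = c(
      "n", "mean", "median", "sd", "range", "min", "max",
      "mr_bar_min", "mr_bar_max", "mr_bar_range",
      "width_min", "width_max", "width_difference",
      "width_difference_over_range",
      paste0("flagged_", x$flagged_counts$scheme)
    ),
    value = c(
      x$n, x$data_summary$mean, x$data_summary$median, x$data_summary$sd,
      x$data_summary$range, x$data_summary$min, x$data_summary$max,
      x$extremal$mr_bar_min, x$extremal$mr_bar_max,
      x$extremal$mr_bar_max - x$extremal$mr_bar_min,
      x$width_min, x$width_max, x$width_difference,
      x$width_difference_over_range,
      as.numeric(x$flagged_counts$flagged)
    )
  )
}

#' @exportS3Method generics::glance
glance.ambiguity_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    mr_bar_min = x$extremal$mr_bar_min,
    mr_bar_max = x$extremal$mr_bar_max,
    width_difference = x$width_difference,
    width_difference_over_range = x$width_difference_over_range,
    orderings_total = x$orderings_total,
    recommendation = x$recommendation
  )
}

report_to_list <- function(report) {
  r <- unclass(report)
  r$extremal <- unclass(r$extremal)
  r$extremal$parity_case <- as.character(r$extremal$parity_case)
  if (!is.null(r$resample)) r$resample <- unclass(r$resample)
  r
}

#' Write / read an ambiguity report
#'
#' `write_report()` serialises a report to JSON (lossless round-trip, full
#' precision), CSV (one row per named statistic) or plain text (statistics
#' displayed at 3 significant figures).  `read_report()` reads the JSON form
#' back into an `ambiguity_report`.
#'
#' @param report An `ambiguity_report` from [build_report()].
#' @param path Output (input) file path.
#' @param format `"json"`, `"csv"` or `"text"`.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns an `ambiguity_report`.
#' @export
write_report <- function(report, path, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path,
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  } else if (format == "csv") {
    readr::write_csv(tidy(report), path)
  } else {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  r$data_summary <- tibble::as_tibble(r$data_summary)
  r$flagged_counts <- tibble::as_tibble(r$flagged_counts)
  for (f in c("limits_min", "limits_max", "fences_inner", "fences_outer", "sigma")) {
    r[[f]] <- tibble::as_tibble(r[[f]])
  }
  r$extremal <- structure(r$extremal, class = "mr_extrema")
  if (!is.null(r$resample)) {
    r$resample <- structure(r$resample, class = "mr_resample")
  }
  structure(r, class = "ambiguity_report")
}

#' Export a plot-ready chart table
#'
#' Writes a CSV with one row per observation (`index`, `label`, `value`) and
#' one column per bound of every scheme in the report (XmR limits at each
#' extreme, inner/outer fences, sigma limits), plus `clipped_*` flags
#' marking bounds that fall outside \[0, 100\] for percentage data -- those
#' are the bounds a chart of bounded data would not draw.
#'
#' @param data The [observation_set()] the report was built from.
#' @param report An `ambiguity_report`.
#' @param path Output CSV path.
#' @return The exported tibble, invisibly.
#' @export
chart_export <- function(data, report, path) {
  x <- obs_values(data)
  out <- tibble::tibble(
    index = seq_along(x),
    label = obs_labels(data),
    value = x,
    xmr_min_lower = report$limits_min$lower,
    xmr_min_upper = report$limits_min$upper,
    xmr_max_lower = report$limits_max$lower,
    xmr_max_upper = report$limits_max$upper,
    inner_fence_lower = report$fences_inner$lower,
    inner_fence_upper = report$fences_inner$upper,
    outer_fence_lower = report$fences_outer$lower,
    outer_fence_upper = report$fences_outer$upper,
    sigma_lower = report$sigma$lower,
    sigma_upper = report$sigma$upper
  )
  bound_cols <- setdiff(names(out), c("index", "label", "value"))
  for (col in bound_cols) {
    out[[paste0("clipped_", col)]] <- out[[col]] < 0 | out[[col]] > 100
  }
  readr::write_csv(out, path)
  invisible(out)
}

#' Chart of the data with all bounds superimposed
#'
#' ggplot2 rendering of the report: the observations in their current
#' (original) order with horizontal lines for the XmR limits at each
#' extremal average moving range, Tukey's inner and outer fences, and the
#' 3-sigma limits.  For percentage-scale data, bounds outside \[0, 100\] are
#' drawn anyway; clip them with ggplot2 coordinates if desired.
#'
#' @param object An `ambiguity_report`.
#' @param data The observation set the report was built from (required for
#'   the points).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ambiguity_report <- function(object, data, ...) {
  x <- obs_values(data)
  pts <- tibble::tibble(index = seq_along(x), value = x)
  bounds <- tibble::tibble(
    scheme = rep(
      c("XmR at mR-bar min", "XmR at mR-bar max", "inner fences", "outer fences", "3-sigma"),
      each = 2
    ),
    bound = c(
      object$limits_min$lower, object$limits_min$upper,
      object$limits_max$lower, object$limits_max$upper,
      object$fences_inner$lower, object$fences_inner$upper,
      object$fences_outer$lower, object$fences_outer$upper,
      object$sigma$lower, object$sigma$upper
    )
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = bounds,
      ggplot2::aes(yintercept = .data$bound, colour = .data$scheme),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "observation", y = object$unit_label,
      colour = "scheme",
      title = "Order-dependence of XmR control limits"
    ) +
    ggplot2::theme_minimal()
}
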