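#' Synthetic bounded percentage compliance data
#'
#' Generates a reproducible set of right-skewed percentage measurements on
#' the 0-100 scale, standing in for per-ward policy-compliance rates whose
#' raw values are not published.  The default family is a lognormal clipped
#' from above at 100, with median exp(meanlog) = 27.9% and mean about 33%,
#' so the sample mean reliably exceeds the sample median; the skew matters
#' because it is what makes quartile-based fences, rather than symmetric
#' sigma limits, the appropriate order-free screen.  Other families cover
#' milder skew, degenerate and stress cases for testing.
#'
#' Families and their `params` (all values bounded to `[0, 100]`):
#' \describe{
#'   \item{lognormal_clipped}{`meanlog` (default log(27.9)), `sdlog`
#'     (default 0.6); values clipped from above at 100.}
#'   \item{beta_scaled}{`shape1` (default 2), `shape2` (default 3.93);
#'     values are `100 * rbeta(n, shape1, shape2)` (mean 2/5.93, about
#'     33.7%; mildly right-skewed).}
#'   \item{uniform}{`min` (default 0), `max` (default 100).}
#'   \item{constant}{`value` (default 50); every observation equal.}
#' }
#'
#' @param n Number of observations (default 23 wards).
#' @param seed Integer seed; identical inputs give identical output.
#' @param family Distribution family, see Details.
#' @param params Named list overriding the family defaults.
#' @return An [observation_set()] with labels `ward_01`, ..., unordered,
#'   unit `"% compliance"`.
#' @examples
#' generate_compliance_data(n = 23, seed = 1)
#' generate_compliance_data(n = 5, family = "constant")
#' @export
generate_compliance_data <- function(n = 23, seed = 1L,
                                     family = c(
                                       "lognormal_clipped", "beta_scaled",
                                       "uniform", "constant"
                                     ),
                                     params = list()) {
  family <- match.arg(family)
  if (n < 2) stop("insufficient data: need n >= 2", call. = FALSE)
  defaults <- switch(family,
    beta_scaled = list(shape1 = 2, shape2 = 3.93),
    lognormal_clipped = list(meanlog = log(27.9), sdlog = 0.6),
    uniform = list(min = 0, max = 100),
    constant = list(value = 50)
  )
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) {
    stop(
      "invalid params for family `", family, "`: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  p <- utils::modifyList(defaults, params)
  values <- withr::with_seed(seed, switch(family,
    beta_scaled = {
      if (p$shape1 <= 0 || p$shape2 <= 0) {
        stop("beta shapes must be positive", call. = FALSE)
      }
      100 * stats::rbeta(n, p$shape1, p$shape2)
    },
    lognormal_clipped = {
      if (p$sdlog <= 0) stop("sdlog must be positive", call. = FALSE)
      pmin(stats::rlnorm(n, p$meanlog, p$sdlog), 100)
    },
    uniform = {
      if (p$min > p$max || p$min < 0 || p$max > 100) {
        stop("uniform bounds must satisfy 0 <= min <= max <= 100", call. = FALSE)
      }
      stats::runif(n, p$min, p$max)
    },
    constant = {
      if (p$value < 0 || p$value > 100) {
        stop("constant value must lie in [0, 100]", call. = FALSE)
      }
      rep(p$value, n)
    }
  ))
  observation_set(values,
    labels = sprintf("ward_%0*d", max(2L, nchar(n)), seq_len(n)),
    ordered = FALSE, unit = "% compliance"
  )
}

#' Canonical small fixtures with oracle-verified extrema
#'
#' A fixed battery of tiny data sets chosen to hit every branch of the
#' closed-form maximum: odd n with the upper central gap dominant, odd n
#' with the lower central gap dominant, even n, all-tied values, and the
#' degenerate n = 2 case.  Each fixture's extrema are computed at call time
#' by the exhaustive oracle ([brute_force_extrema()]), never hand-entered,
#' so the oracle remains the single source of truth.
#'
#' @return A named list; each element has `data` (an [observation_set()])
#'   and `extremal` (the oracle's `mr_extrema` result).
#' @examples
#' fx <- canonical_fixtures()
#' fx$odd_upper_gap$extremal$s_max # 5 for values 0, 1, 3
#' @export
canonical_fixtures <- function() {
  sets <- list(
    odd_upper_gap = c(0, 1, 3),
    odd_lower_gap = c(0, 3, 4),
    even = c(0, 1, 2, 4),
    ties = c(5, 5, 5),
    degenerate_n2 = c(1, 2)
  )
  lapply(sets, function(v) {
    list(
      data = observation_set(v, ordered = FALSE),
      extremal = brute_force_extrema(v)
    )
  })
}
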