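#' Attribute-chart control limits (p, np, c, u)
#'
#' Minimal Shewhart 3-sigma attribute-chart limits, included to make the
#' permutation-invariance of these charts demonstrable alongside the
#' order-dependence of the XmR chart.  p- and np-charts assume binomial
#' variation in the proportion / number of nonconforming units; c- and
#' u-charts assume Poisson variation in counts of events.  All four pool a
#' single centre from the data, so their limits depend only on the multiset
#' of (count, size) pairs, never on subgroup order.
#'
#' Centre and limits:
#' \describe{
#'   \item{p}{centre p = sum(counts)/sum(sizes); limits p +/-
#'     3*sqrt(p(1-p)/size_i), one row per subgroup (stair-step when sizes
#'     vary).}
#'   \item{np}{requires a constant subgroup size m; centre m*p; limits
#'     m*p +/- 3*sqrt(m*p(1-p)); a single row.}
#'   \item{c}{centre c = mean(counts); limits c +/- 3*sqrt(c); a single
#'     row.}
#'   \item{u}{centre u = sum(counts)/sum(sizes); limits u +/-
#'     3*sqrt(u/size_i), one row per subgroup.}
#' }
#' Raw lower limits are retained; `lower_clipped_at_zero` marks those below
#' zero, whose interpretive bound is 0.
#'
#' @param counts Non-negative integer events/faults per subgroup.
#' @param sizes Subgroup sizes (required for p, np, u; must be absent for
#'   c).  For p/np, `counts <= sizes` elementwise.
#' @param kind Chart kind: `"p"`, `"np"`, `"c"` or `"u"`.
#' @return A control-limits tibble (columns `chart_kind`, `subgroup`,
#'   `center`, `lower`, `upper`, `width`, `lower_clipped_at_zero`): one row
#'   per subgroup for p and u, a single row (subgroup `NA`) for np and c.
#' @examples
#' attribute_limits(c(4, 4, 4), kind = "c") # centre 4, limits -2 and 10
#' attribute_limits(c(1, 1), sizes = c(10, 10), kind = "p")
#' @export
attribute_limits <- function(counts, sizes = NULL, kind = c("p", "np", "c", "u")) {
  kind <- match.arg(kind)
  if (length(counts) < 1 || any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (kind == "c") {
    if (!is.null(sizes)) {
      stop("sizes are not used for c-charts", call. = FALSE)
    }
  } else {
    if (is.null(sizes)) {
      stop("sizes are required for ", kind, "-charts", call. = FALSE)
    }
    if (length(sizes) != length(counts)) {
      stop("counts and sizes must have the same length", call. = FALSE)
    }
    if (any(sizes <= 0) || anyNA(sizes)) {
      stop("sizes must be positive and complete", call. = FALSE)
    }
    if (kind %in% c("p", "np") && any(counts > sizes)) {
      stop("counts cannot exceed sizes for ", kind, "-charts", call. = FALSE)
    }
  }
  res <- switch(kind,
    p = {
      pbar <- sum(counts) / sum(sizes)
      se <- 3 * sqrt(pbar * (1 - pbar) / sizes)
      control_limits_row("p", pbar, pbar - se, pbar + se) |>
        dplyr::mutate(subgroup = seq_along(counts), .after = "chart_kind")
    },
    np = {
      if (length(unique(sizes)) != 1) {
        stop("np-charts require a constant subgroup size", call. = FALSE)
      }
      m <- sizes[1]
      pbar <- sum(counts) / sum(sizes)
      se <- 3 * sqrt(m * pbar * (1 - pbar))
      control_limits_row("np", m * pbar, m * pbar - se, m * pbar + se) |>
        dplyr::mutate(subgroup = NA_integer_, .after = "chart_kind")
    },
    c = {
      cbar <- mean(counts)
      se <- 3 * sqrt(cbar)
      control_limits_row("c", cbar, cbar - se, cbar + se) |>
        dplyr::mutate(subgroup = NA_integer_, .after = "chart_kind")
    },
    u = {
      ubar <- sum(counts) / sum(sizes)
      se <- 3 * sqrt(ubar / sizes)
      control_limits_row("u", ubar, ubar - se, ubar + se) |>
        dplyr::mutate(subgroup = seq_along(counts), .after = "chart_kind")
    }
  )
  res
}
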