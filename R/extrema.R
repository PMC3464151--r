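#' Gaps between consecutive order statistics
#'
#' Sorts the values non-descending and returns the successive gaps
#' delta_j = x_(j+1) - x_(j), the substrate of the closed-form extrema of
#' the average moving range.  The gaps are non-negative and sum to the data
#' range.
#'
#' @inheritParams moving_ranges
#' @return A list of class `delta_vector`: `sorted_values` (non-descending)
#'   and `deltas` (length n-1).
#' @examples
#' delta_vector(c(3, 0, 1))$deltas # 1, 2
#' @export
delta_vector <- function(data) {
  x <- obs_values(data)
  check_n(x)
  s <- sort(x)
  structure(list(sorted_values = s, deltas = diff(s)), class = "delta_vector")
}

# Coefficient vector c_j such that S_max = sum c_j * delta_j.
# n even: (2, 4, ..., n-2, n-1, n-2, ..., 4, 2), peak n-1 at j = n/2.
# n odd: outer coefficients 2, 4, ..., n-3 ascending then descending; the
# two central coefficients are (n-2, n-1) when the upper central gap is at
# least the lower one, else (n-1, n-2).  When the central gaps are equal the
# two assignments give the same total.  n = 2: the single gap has
# coefficient 1 (S_max = S_min = delta_1).
s_max_coefficients <- function(deltas) {
  n <- length(deltas) + 1L
  if (n == 2) {
    return(1)
  }
  j <- seq_len(n - 1L)
  if (n %% 2L == 0L) {
    m <- n %/% 2L
    ifelse(j < m, 2 * j, ifelse(j == m, n - 1, 2 * (n - j)))
  } else {
    m <- (n - 1L) %/% 2L # lower central gap index; upper is m + 1
    co <- ifelse(j < m, 2 * j, ifelse(j > m + 1L, 2 * (n - j), NA_real_))
    if (deltas[m + 1L] >= deltas[m]) {
      co[m] <- n - 2
      co[m + 1L] <- n - 1
    } else {
      co[m] <- n - 1
      co[m + 1L] <- n - 2
    }
    co
  }
}

parity_case_of <- function(deltas) {
  n <- length(deltas) + 1L
  if (n == 2L) {
    "degenerate_n2"
  } else if (n %% 2L == 0L) {
    "even"
  } else {
    m <- (n - 1L) %/% 2L
    if (deltas[m + 1L] >= deltas[m]) "odd_upper_gap" else "odd_lower_gap"
  }
}

#' Extremal sums of moving ranges over all orderings
#'
#' Over the (at most n!) orderings of a data set, the sum S of the n-1
#' moving ranges attains a minimum S_min = x_(n) - x_(1) -- the sorted order
#' spreads the total range over all gaps -- and a maximum S_max given in
#' closed form as a weighted sum of the sorted-value gaps, with weights
#' depending on the parity of n (and, for odd n, on which central gap is
#' larger).  The extremal average moving ranges are these sums divided by
#' n-1.  `s_min()` and `s_max()` return the sums; [mr_extrema()] returns the
#' full result including achieving orderings.
#'
#' @inheritParams moving_ranges
#' @return `s_min()`, `s_max()`: a single number; `s_max()` carries the
#'   branch used in attribute `parity_case`
#'   (`"odd_upper_gap"`, `"odd_lower_gap"`, `"even"`, `"degenerate_n2"`).
#' @examples
#' s_min(c(0, 1, 3)) # 3
#' s_max(c(0, 1, 3)) # 5 = 1*1 + 2*2
#' @export
s_min <- function(data) {
  x <- obs_values(data)
  check_n(x)
  max(x) - min(x)
}

#' @rdname s_min
#' @export
s_max <- function(data) {
  d <- delta_vector(data)$deltas
  structure(sum(s_max_coefficients(d) * d),
    parity_case = parity_case_of(d)
  )
}

# Zigzag construction of an ordering attaining S_max.  Writing S as a signed
# weighted sum of the values (interior peaks +2, interior valleys -2,
# endpoints +/-1), the optimum puts the lower half of the sorted values in
# the valleys and the upper half on the peaks, "wasting" the weakest weight
# on the least extreme candidates:
#   n even: endpoints are the largest low value and the smallest high value;
#   n odd, upper central gap >= lower: the median joins the lower half and
#     both endpoints are the two largest low values;
#   n odd, otherwise: mirror image (endpoints are the two smallest highs).
# Always verified against the closed form by the caller.
zigzag_max_ordering <- function(sorted) {
  n <- length(sorted)
  if (n == 2L) {
    return(sorted)
  }
  y <- numeric(n)
  if (n %% 2L == 0L) {
    m <- n %/% 2L
    lo <- sorted[1:m]
    hi <- sorted[(m + 1L):n]
    valleys <- c(lo[m], lo[seq_len(m - 1L)])
    peaks <- c(hi[seq_len(m)[-1L]], hi[1L])
    y[seq(1L, n, 2L)] <- valleys
    y[seq(2L, n, 2L)] <- peaks
  } else {
    m <- (n + 1L) %/% 2L
    d <- diff(sorted)
    if (d[m] >= d[m - 1L]) {
      lo <- sorted[1:m]
      hi <- sorted[seq_len(n - m) + m]
      valleys <- c(lo[m - 1L], lo[seq_len(max(0L, m - 2L))], lo[m])
      y[seq(1L, n, 2L)] <- valleys
      y[seq(2L, n - 1L, 2L)] <- hi
    } else {
      lo <- sorted[seq_len(m - 1L)]
      hi <- sorted[m:n]
      peaks <- c(hi[1L], if (m >= 3L) hi[3:m], hi[2L])
      y[seq(1L, n, 2L)] <- peaks
      y[seq(2L, n - 1L, 2L)] <- lo
    }
  }
  y
}

#' Orderings attaining the extremal average moving ranges
#'
#' The sorted order attains the minimum.  A maximising ordering is built by
#' the zigzag construction (alternating picks from the lower and upper
#' halves of the sorted values, oriented by the odd-n central-gap rule) and
#' *verified* by evaluating the average moving range on it and comparing
#' with the closed-form maximum to relative tolerance 1e-12; if verification
#' fails the function falls back to exhaustive search for n <= 9 and raises
#' an error otherwise (a failure would signal an implementation bug, never a
#' silently wrong answer).
#'
#' @inheritParams moving_ranges
#' @return A list with `min_ordering` and `max_ordering`, each a permutation
#'   of the input values.
#' @examples
#' extremal_orderings(c(0, 1, 3))$max_ordering # e.g. 0 3 1, mR-bar 2.5
#' @export
extremal_orderings <- function(data) {
  x <- obs_values(data)
  check_n(x)
  s <- sort(x)
  n <- length(x)
  smax <- as.numeric(s_max(x))
  y <- zigzag_max_ordering(s)
  achieved <- sum(abs(diff(y)))
  tol <- 1e-12 * max(1, abs(smax))
  if (abs(achieved - smax) > tol) {
    if (n <= 9L) {
      y <- brute_force_extrema(x)$max_ordering
    } else {
      stop("max ordering construction failed", call. = FALSE)
    }
  }
  list(min_ordering = s, max_ordering = y)
}

# All permutations of 1..n as an integer matrix (n! rows).  Recursive
# construction; intended only for the exhaustive oracle (n <= 9).
permutation_matrix <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  p <- permutation_matrix(n - 1L)
  k <- nrow(p)
  out <- matrix(0L, n * k, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * k + 1L):(i * k)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[p], k, n - 1L)
  }
  out
}

#' Exhaustive permutation oracle for the extrema
#'
#' Enumerates every ordering of the values (exploiting the reversal symmetry
#' of the average moving range, so n!/2 evaluations) and returns the exact
#' minimum and maximum together with achieving orderings.  This is the
#' numerical ground truth against which the closed forms and the zigzag
#' construction are verified; it is capped at n <= 9 (9!/2 = 181,440
#' evaluations) to guard against factorial blow-up.
#'
#' @inheritParams moving_ranges
#' @return An object of class `mr_extrema` (see [mr_extrema()]) with
#'   `method = "brute_force"`.
#' @examples
#' brute_force_extrema(c(0, 1, 2, 4))$mr_bar_max # 3
#' @export
brute_force_extrema <- function(data) {
  x <- obs_values(data)
  check_n(x)
  n <- length(x)
  if (n > 9L) {
    stop("instance too large for exhaustive oracle (n > 9)", call. = FALSE)
  }
  perms <- permutation_matrix(n)
  perms <- perms[perms[, 1L] < perms[, n], , drop = FALSE] # reversal symmetry
  yy <- matrix(x[perms], nrow(perms), n)
  ss <- rowSums(abs(yy[, -1L, drop = FALSE] - yy[, -n, drop = FALSE]))
  i_min <- which.min(ss)
  i_max <- which.max(ss)
  d <- delta_vector(x)$deltas
  new_mr_extrema(
    values = x, n = n,
    s_min = ss[i_min], s_max = ss[i_max],
    min_ordering = yy[i_min, ], max_ordering = yy[i_max, ],
    parity_case = parity_case_of(d), method = "brute_force"
  )
}

new_mr_extrema <- function(values, n, s_min, s_max, min_ordering,
                           max_ordering, parity_case, method) {
  structure(
    list(
      values = values, n = n,
      s_min = s_min, s_max = s_max,
      mr_bar_min = s_min / (n - 1), mr_bar_max = s_max / (n - 1),
      min_ordering = min_ordering, max_ordering = max_ordering,
      parity_case = parity_case, method = method
    ),
    class = "mr_extrema"
  )
}

#' Extremal average moving ranges of a data set
#'
#' Computes the minimum and maximum average moving range attainable by any
#' ordering of the data, via the closed forms (default) or the exhaustive
#' oracle, together with orderings achieving each extreme.  The spread
#' between the two is the ambiguity a practitioner faces when placing
#' unordered data on an XmR chart.
#'
#' @inheritParams moving_ranges
#' @param method `"closed_form"` (any n) or `"brute_force"` (n <= 9).
#' @return An object of class `mr_extrema`: a list with `s_min`, `s_max`,
#'   `mr_bar_min`, `mr_bar_max`, `min_ordering`, `max_ordering`, `n`,
#'   `parity_case`, `method`.  Has [tidy()], [glance()] and print methods.
#' @examples
#' ext <- mr_extrema(c(0, 1, 2, 4))
#' ext$mr_bar_max # 3
#' glance(ext)
#' @export
mr_extrema <- function(data, method = c("closed_form", "brute_force")) {
  method <- match.arg(method)
  if (method == "brute_force") {
    return(brute_force_extrema(data))
  }
  x <- obs_values(data)
  check_n(x)
  n <- length(x)
  d <- delta_vector(x)$deltas
  smax <- as.numeric(s_max(x))
  ords <- extremal_orderings(x)
  new_mr_extrema(
    values = x, n = n,
    s_min = s_min(x), s_max = smax,
    min_ordering = ords$min_ordering, max_ordering = ords$max_ordering,
    parity_case = parity_case_of(d), method = "closed_form"
  )
}

#' Spread of the average moving range over orderings
#'
#' Returns mR-bar_max - mR-bar_min.  As a self-check it also asserts the
#' coefficient-reduction identity S_max - S_min = sum (c_j - 1) delta_j
#' (the range of the data is sum delta_j, so subtracting one from every
#' closed-form coefficient yields the difference exactly).
#'
#' @inheritParams moving_ranges
#' @return A single number, the attainable spread of the average moving
#'   range.
#' @examples
#' mr_bar_range(c(0, 1, 2, 4)) # (9 - 4) / 3
#' @export
mr_bar_range <- function(data) {
  x <- obs_values(data)
  check_n(x)
  d <- delta_vector(x)$deltas
  co <- s_max_coefficients(d)
  smax <- sum(co * d)
  smin <- max(x) - min(x)
  identity_gap <- abs((smax - smin) - sum((co - 1) * d))
  stopifnot(identity_gap <= 1e-9 * max(1, smax))
  (smax - smin) / (length(x) - 1)
}

#' @export
print.mr_extrema <- function(x, ...) {
  cat(
    "Extremal average moving ranges (n = ", x$n, ", ", x$method, ")\n",
    "  mR-bar min: ", format_sig(x$mr_bar_min),
    "   (S_min = ", format_sig(x$s_min), ", sorted order)\n",
    "  mR-bar max: ", format_sig(x$mr_bar_max),
    "   (S_max = ", format_sig(x$s_max),
    ", case ", x$parity_case, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mr_extrema <- function(x, ...) {
  tibble::tibble(
    statistic = c("s_min", "s_max", "mr_bar_min", "mr_bar_max"),
    value = c(x$s_min, x$s_max, x$mr_bar_min, x$mr_bar_max)
  )
}

#' @exportS3Method generics::glance
glance.mr_extrema <- function(x, ...) {
  tibble::tibble(
    n = x$n, parity_case = x$parity_case, method = x$method,
    s_min = x$s_min, s_max = x$s_max,
    mr_bar_min = x$mr_bar_min, mr_bar_max = x$mr_bar_max,
    mr_bar_range = x$mr_bar_max - x$mr_bar_min
  )
}
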