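---
title: "Ordering ambiguity in XmR charts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering ambiguity in XmR charts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmrorder)
```

## The problem

The individuals and moving range (XmR) chart is the workhorse of statistical
process control when distributional assumptions cannot be justified, as is
typical for healthcare quality measures.  Its dispersion estimate is the
average moving range

$$\bar{mR} = \frac{1}{n-1}\sum_{j=1}^{n-1} |y_{j+1} - y_j|,$$

computed over the data *in a specific order* $y_1,\dots,y_n$, and the
individuals-chart limits are $\bar{x} \pm 2.66\,\bar{mR}$.  For a time
series the order is given.  For logically comparable data with no inherent
order — say, annual per-ward compliance percentages — any of the $n!$
orderings could be chosen, and each ordering yields its own $\bar{mR}$ and
hence its own control limits.  This package quantifies that ambiguity
exactly and implements the order-free alternatives appropriate when no
ordering exists.

## Extremal average moving ranges

Label the data non-descending, $x_1 \le \dots \le x_n$, and let
$\delta_j = x_{j+1} - x_j$ be the gaps.  Write $S$ for the sum of moving
ranges, so $\bar{mR} = S/(n-1)$.

* **Minimum.** The sorted order telescopes: every gap is traversed once, so
  $S_{\min} = x_n - x_1$ and $\bar{mR}_{\min} = (x_n - x_1)/(n-1)$.
* **Maximum.** $S_{\max}$ is a weighted sum $\sum_j c_j \delta_j$ with a
  tent-shaped coefficient vector.  For $n$ even the coefficients are
  $(2, 4, \dots, n-2,\ n-1,\ n-2, \dots, 4, 2)$.  For $n$ odd the outer
  coefficients are $(2, 4, \dots, n-3)$ ascending and then descending, and
  the two central gaps receive $(n-2, n-1)$ when the upper central gap is at
  least the lower one, $(n-1, n-2)$ otherwise; when the central gaps are
  equal the two assignments coincide.  For $n = 2$ the single gap has
  coefficient 1 and the extrema collapse.
* **Difference.** Since $\sum_j \delta_j = x_n - x_1$, reducing every
  coefficient by one gives $S_{\max} - S_{\min}$ exactly; `mr_bar_range()`
  asserts this identity on every call.

The comparison of the central gaps uses exact `>=`; no tolerance is needed
because at equality both branches evaluate to the same number (tested).

### The maximising ordering

The closed forms give the extremal *values* but not an ordering attaining
the maximum.  `extremal_orderings()` constructs one by a zigzag argument:
in any ordering, $S$ is a signed weighted sum of the values in which
interior local maxima count $+2$, interior local minima $-2$, and the two
endpoints $\pm 1$.  The construction therefore places the lower half of the
sorted values in the valleys and the upper half on the peaks, and spends
the weaker endpoint weights on the least extreme candidates: for $n$ even
the endpoints are the largest low value and the smallest high value; for
$n$ odd the median joins whichever half the central-gap rule dictates and
the endpoints are the two weakest members of the larger half.  Because this
construction is our own design choice, it is never trusted: every call
evaluates the average moving range of the constructed ordering and compares
it with the closed-form maximum at relative tolerance $10^{-12}$, falling
back to exhaustive search for $n \le 9$ and raising an error for larger $n$
rather than returning silently wrong output.

### Numerical verification in place of proof

The closed forms are verified against an exhaustive permutation oracle
(`brute_force_extrema()`), which enumerates all orderings with the reversal
symmetry factored out ($n!/2$ evaluations) and is capped at $n \le 9$.  The
test suite runs the oracle against the closed forms on a seeded grid of
1,200 data sets for $n \in \{3,\dots,8\}$, a third of them integer-valued
with ties and a quarter engineered to have exactly equal central gaps;
agreement is exact on integer data and within $10^{-12}$ relative on real
data.  A symbolic proof of the coefficient formulas is out of scope.

## Resampling the statistic

`sample_orderings()` draws independent uniformly random permutations
(R's Fisher–Yates `sample()` under Mersenne–Twister, seeded) and records
$\bar{mR}$ for each — each sampled ordering contains every datum exactly
once, while orderings are drawn with replacement from the population of
orderings.  The default of 16,383 resamples is configurable.  Summary
percentiles use linear interpolation between order statistics
(`quantile()` type 7); the convention is stated because quartile and
percentile conventions differ between software.  A single-element
distribution reports a standard deviation of 0 with a warning rather than
an error.  For $n \le 6$ the sampled extremes provably reach the
closed-form envelope in practice (few distinct values, many draws), which
the tests exercise; every sampled value is guaranteed to lie inside
$[\bar{mR}_{\min}, \bar{mR}_{\max}]$.

## Order-free alternatives

For data without an inherent order the problem is outlier detection, not
control charting:

* **Tukey's fences** at $Q_1 - k(Q_3 - Q_1)$ and $Q_3 + k(Q_3 - Q_1)$, with
  $k = 1.5$ (inner) and $k = 3$ (outer).  The default quartile convention
  is Tukey hinges (medians of the lower and upper halves, halves including
  the overall median for odd $n$, via `fivenum()`); an interpolation
  convention (type-7 quantiles) is selectable, and reports record which
  convention produced their numbers.  Hinges are the default because the
  fences are Tukey's method; the choice matters for small $n$.
* **Average-and-SD (3-sigma) chart**: mean $\pm$ 3 sample standard
  deviations ($n-1$ denominator).  Appropriate for roughly symmetric data;
  the report raises a skewness advisory (mean > median) suggesting fences
  instead, but never switches methods silently.

Both are permutation-invariant by construction, which the tests assert over
random shuffles, along with location–scale equivariance and the nesting of
outer-fence flags inside inner-fence flags.

p-, np-, c- and u-chart limits (binomial and Poisson 3-sigma closed forms,
pooled centre) are included at the minimal depth needed to demonstrate that
attribute-chart limits are *exactly* permutation-invariant — the contrast
that makes the XmR chart's order-dependence notable.  They are not a full
attribute-chart suite.

## Signal detection conventions

Only rule 1 (point strictly beyond a limit) is implemented; run rules and
zone rules are excluded because the comparison of flagging schemes counts
only beyond-limit points.  Points exactly on a limit are not flagged: the
strict inequality is conservative, documented, and immaterial for
continuous data.  Flagging always uses the raw limits; for percentage data
a negative lower limit is retained alongside a `lower_clipped_at_zero` flag
(the interpretive bound is 0, but clipping before detection would hide the
geometry of the problem).

## The ambiguity report

`build_report()` assembles the whole argument for a data set: summary
statistics; the extrema; the limits and widths at $\bar{mR}_{\min}$ and
$\bar{mR}_{\max}$; the width difference and its ratio to the data range;
the exact count of orderings ($n!$ and the distinct-value bound $n!/2$,
computed in exact big-integer arithmetic because $n!$ exceeds exact double
precision already at $n = 23$); flagged counts under five schemes (XmR at
each extreme, inner and outer fences, 3-sigma); and a recommendation:
XmR for data with an inherent order, an outlier method otherwise.  The
report embeds the constants, quartile convention and seed used, so any
number it shows can be traced to a method disclosure.

## Display rounding

Internal computation is always full precision; JSON and CSV outputs carry
full precision.  Displayed statistics are rounded to 3 significant figures,
and one-decimal values use round-half-to-even applied to the *decimal*
value: `round_dp()` first snaps to 12 significant digits so that a quantity
that is exactly, say, 2.65 in decimal arithmetic rounds to 2.6 rather than
being tipped up by binary representation noise.

## Synthetic data

The raw per-ward compliance values behind the motivating application are
not published, so the package generates its own.  The default family is a
lognormal clipped above at 100, with `meanlog = log(27.9)` (so the
population median is 27.9%) and `sdlog = 0.6` (population mean about 33%):
right-skewed, bounded, with occasional wards near the upper bound.  The
skew is the point — it is what makes quartile-based fences rather than
symmetric sigma limits the appropriate order-free screen, and the generator
contract (sample mean exceeds sample median in well over 90% of seeds at
n = 23) is tested.  A scaled Beta, a uniform and a constant family cover
milder skew, stress and degenerate cases.  What the generator does *not*
emulate: any dependence between wards, measurement error structure,
rounding of reported percentages, or the actual unpublished values — so
passing tests say the methods are correct, not that any specific published
table is reproduced.

## Problem sizes and determinism

The test suite uses the exhaustive oracle up to $n = 8$ (1,200 data sets),
10,000-ordering resampling envelopes over 50 data sets, and 1,000 generator
seeds for the skew contract; these sizes give exact or tight stochastic
checks at interactive runtimes.  Every stochastic component takes an
explicit seed and is bit-for-bit reproducible; no global RNG state is
disturbed (`withr::with_seed`).

## Known limitations

* The closed-form *distribution* of $\bar{mR}$ between its extrema is data
  dependent and is not attempted — only resampling approximates it.
* The exhaustive oracle is capped at $n \le 9$; beyond that, correctness of
  the closed forms rests on the verified construction and the tested grid.
* Attribute charts use normal-approximation limits only (no exact or
  small-sample corrections).
* The Vysochanskii–Petunin variant of the sigma rule is not implemented.
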