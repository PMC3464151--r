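test_that("delta vector sorts and differences the values", {
  dv <- delta_vector(c(3, 0, 1))
  expect_equal(dv$sorted_values, c(0, 1, 3))
  expect_equal(dv$deltas, c(1, 2))
  expect_equal(sum(dv$deltas), 3) # gaps sum to the range

  expect_equal(delta_vector(c(5, 5, 5))$deltas, c(0, 0))
  expect_equal(delta_vector(c(75, 16.7))$deltas, 75 - 16.7) # range 58.3
  expect_error(delta_vector(1), "insufficient data")
})

test_that("closed-form extrema match hand values on the canonical fixtures", {
  # n = 3 with dominant upper central gap: S_max = 1*1 + 2*2 = 5
  expect_equal(s_min(c(0, 1, 3)), 3)
  expect_equal(as.numeric(s_max(c(0, 1, 3))), 5)
  expect_equal(attr(s_max(c(0, 1, 3)), "parity_case"), "odd_upper_gap")
  expect_equal(mr_extrema(c(0, 1, 3))$mr_bar_max, 2.5)

  # n = 3 with dominant lower central gap: deltas (3, 1), S_max = 2*3 + 1*1
  expect_equal(as.numeric(s_max(c(0, 3, 4))), 7)
  expect_equal(attr(s_max(c(0, 3, 4)), "parity_case"), "odd_lower_gap")

  # n = 4: coefficients (2, 3, 2) on deltas (1, 1, 2)
  expect_equal(as.numeric(s_max(c(0, 1, 2, 4))), 9)
  expect_equal(mr_extrema(c(0, 1, 2, 4))$mr_bar_max, 3)
  expect_equal(mr_extrema(c(0, 1, 2, 4))$mr_bar_min, 4 / 3)

  # ties and the degenerate pair
  expect_equal(as.numeric(s_max(c(5, 5, 5))), 0)
  expect_equal(mr_extrema(c(1, 2))$parity_case, "degenerate_n2")
  expect_equal(mr_extrema(c(1, 2))$s_max, 1)
  expect_equal(mr_extrema(c(1, 2))$s_min, 1)
})

test_that("closed forms agree with the exhaustive oracle across n and data", {
  for (n in 3:8) {
    for (r in 1:12) {
      seed <- 1000 * n + r
      x <- random_dataset(n, seed, integers = (r %% 2 == 0))
      bf <- brute_force_extrema(x)
      cf <- mr_extrema(x)
      expect_equal(cf$s_max, bf$s_max, tolerance = 1e-12)
      expect_equal(cf$s_min, bf$s_min, tolerance = 1e-12)
    }
  }
})

test_that("package brute force agrees with an independent enumerator", {
  for (v in list(c(0, 1, 3), c(0, 3, 4), c(0, 1, 2, 4), c(2, 7, 1, 8, 3))) {
    ind <- exhaustive_mr_range(v)
    bf <- brute_force_extrema(v)
    expect_equal(bf$mr_bar_min, unname(ind["min"]))
    expect_equal(bf$mr_bar_max, unname(ind["max"]))
  }
})

test_that("equal central gaps make the two odd-n branches coincide", {
  # deltas (2, 2) around the median: both coefficient assignments give 2+4
  x <- c(0, 2, 4)
  expect_equal(as.numeric(s_max(x)), 6)
  expect_equal(as.numeric(s_max(x)), brute_force_extrema(x)$s_max)
  # larger odd case with equal central gaps
  y <- c(0, 1, 3, 5, 6)
  expect_equal(as.numeric(s_max(y)), brute_force_extrema(y)$s_max)
})

test_that("extremal orderings attain the extrema", {
  ords <- extremal_orderings(c(0, 1, 3))
  expect_equal(mr_bar(ords$max_ordering), 2.5)
  expect_equal(ords$min_ordering, c(0, 1, 3))
  expect_equal(extremal_orderings(c(4, 1, 2, 3))$min_ordering, 1:4)

  for (seed in 1:50) {
    n <- 3 + (seed %% 7) # n in 3..9
    x <- random_dataset(n, 7000 + seed, integers = (seed %% 3 == 0))
    got <- extremal_orderings(x)
    bf <- brute_force_extrema(x)
    expect_equal(sort(got$max_ordering), sort(x)) # a true permutation
    expect_equal(mr_bar(got$max_ordering), bf$mr_bar_max, tolerance = 1e-12)
    expect_equal(mr_bar(got$min_ordering), bf$mr_bar_min, tolerance = 1e-12)
  }
})

test_that("any ordering is sandwiched between the extrema", {
  for (seed in 1:30) {
    x <- random_dataset(10, 300 + seed)
    ext <- mr_extrema(x)
    for (k in 1:20) {
      y <- withr::with_seed(seed * 100 + k, sample(x))
      m <- mr_bar(y)
      expect_gte(m, ext$mr_bar_min - 1e-12)
      expect_lte(m, ext$mr_bar_max + 1e-12)
    }
  }
})

test_that("coefficient vectors have the stated symmetry", {
  co_even <- xmrorder:::s_max_coefficients(rep(1, 7)) # n = 8
  expect_equal(co_even, rev(co_even)) # palindromic
  expect_equal(co_even, c(2, 4, 6, 7, 6, 4, 2))

  co_odd <- xmrorder:::s_max_coefficients(rep(1, 6)) # n = 7, equal centres
  expect_equal(co_odd[-c(3, 4)], rev(co_odd)[-c(3, 4)]) # palindromic outside centre
  expect_equal(sort(co_odd[3:4]), c(5, 6))
})

test_that("extrema are scale- and shift-equivariant", {
  x <- random_dataset(9, 42)
  base <- mr_extrema(x)
  shifted <- mr_extrema(x + 17)
  scaled <- mr_extrema(3 * x)
  neg <- mr_extrema(-2 * x)
  expect_equal(shifted$s_max, base$s_max)
  expect_equal(shifted$s_min, base$s_min)
  expect_equal(scaled$s_max, 3 * base$s_max)
  expect_equal(neg$s_max, 2 * base$s_max)
  expect_equal(neg$s_min, 2 * base$s_min)
})

test_that("mr_bar_range returns the spread and checks the reduction identity", {
  expect_equal(mr_bar_range(c(0, 1, 2, 4)), (9 - 4) / 3)
  expect_equal(mr_bar_range(c(7, 7, 7)), 0)
  # S_max - S_min = sum (c_j - 1) delta_j, hand-checked for {0,1,2,4}:
  # (2-1)*1 + (3-1)*1 + (2-1)*2 = 5 = 9 - 4
  expect_equal(
    as.numeric(s_max(c(0, 1, 2, 4))) - s_min(c(0, 1, 2, 4)), 5
  )
})

test_that("the exhaustive oracle enforces its size guard", {
  expect_error(brute_force_extrema(1:10), "too large")
  expect_error(mr_extrema(1), "insufficient data")
})

test_that("mr_extrema accessors tidy and glance are consistent", {
  ext <- mr_extrema(c(0, 1, 2, 4))
  td <- tidy(ext)
  expect_equal(td$value[td$statistic == "s_max"], 9)
  gl <- glance(ext)
  expect_equal(gl$mr_bar_range, 3 - 4 / 3)
  expect_equal(gl$parity_case, "even")
})
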