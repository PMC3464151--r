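test_that("hinge quartiles match the hand rule", {
  expect_equal(quartiles(c(1, 2, 3, 4)), c(q1 = 1.5, q3 = 3.5))
  # odd n: halves include the overall median
  expect_equal(quartiles(1:5), c(q1 = 2, q3 = 4))
  expect_equal(quartiles(c(6, 6, 6)), c(q1 = 6, q3 = 6))
  # the interpolation convention differs where hinges sit between points
  expect_equal(
    quartiles(c(1, 2, 3, 4), method = "interpolation"),
    c(q1 = 1.75, q3 = 3.25)
  )
})

test_that("fences follow Q1 - k*IQR and Q3 + k*IQR", {
  f <- tukey_fences(c(1, 2, 3, 4), k = 1.5)
  expect_equal(f$lower, -1.5)
  expect_equal(f$upper, 6.5)
  expect_equal(f$iqr, 2)
  expect_equal(f$kind, "inner")
  expect_equal(tukey_fences(c(1, 2, 3, 4), k = 3)$kind, "outer")

  collapsed <- tukey_fences(c(1, 2, 3, 4), k = 0)
  expect_equal(collapsed$lower, collapsed$q1)
  expect_equal(collapsed$upper, collapsed$q3)
  expect_equal(collapsed$kind, "custom")
  expect_error(tukey_fences(c(1, 2), k = -1), "non-negative")
})

test_that("inner fence interval is contained in the outer fence interval", {
  for (seed in 1:40) {
    x <- random_dataset(11, 500 + seed)
    inner <- tukey_fences(x, 1.5)
    outer <- tukey_fences(x, 3)
    expect_lte(outer$lower, inner$lower)
    expect_gte(outer$upper, inner$upper)
  }
})

test_that("sigma limits use the sample standard deviation", {
  lim <- sigma_limits(c(0, 10))
  expect_equal(lim$center, 5)
  expect_equal(lim$lower, 5 - 3 * 10 / sqrt(2)) # sd of two points |x1-x2|/sqrt(2)
  expect_equal(lim$upper, 5 + 3 * 10 / sqrt(2))
  expect_equal(lim$chart_kind, "average_sd")

  expect_equal(sigma_limits(c(7, 7, 7))$width, 0)
  zero <- sigma_limits(c(1, 5), n_sigma = 0)
  expect_equal(zero$lower, zero$center)
})

test_that("flagging works on the canonical fixture and respects nesting", {
  x <- c(1, 2, 3, 4, 100) # hinges 2 and 4, inner upper fence 7
  flagged <- flag_outliers(x, tukey_fences(x, 1.5))
  expect_equal(flagged$index, 5)
  expect_equal(flagged$value, 100)

  inside <- c(10, 12, 14, 16)
  expect_equal(nrow(flag_outliers(inside, tukey_fences(inside, 1.5))), 0)

  for (seed in 1:100) {
    y <- withr::with_seed(900 + seed, c(runif(9, 0, 50), runif(2, 0, 500)))
    fo <- flag_outliers(y, tukey_fences(y, 3))$index
    fi <- flag_outliers(y, tukey_fences(y, 1.5))$index
    expect_true(all(fo %in% fi))
  }
})

test_that("fences and sigma limits are permutation-invariant", {
  x <- random_dataset(14, 77)
  base_f <- tukey_fences(x, 1.5)
  base_s <- sigma_limits(x)
  for (k in 1:25) {
    y <- withr::with_seed(k, sample(x))
    expect_equal(tukey_fences(y, 1.5), base_f)
    expect_equal(sigma_limits(y), base_s)
  }
})

test_that("fences are location-scale equivariant", {
  x <- random_dataset(9, 13)
  a <- 2.5
  b <- -7
  f <- tukey_fences(x, 1.5)
  g <- tukey_fences(a * x + b, 1.5)
  expect_equal(g$lower, a * f$lower + b)
  expect_equal(g$upper, a * f$upper + b)
  s <- sigma_limits(x)
  t <- sigma_limits(a * x + b)
  expect_equal(t$lower, a * s$lower + b)
  expect_equal(t$upper, a * s$upper + b)
})
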