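test_that("orderings are counted in exact integer arithmetic", {
  expect_equal(orderings_count(3)$total, "6")
  expect_equal(orderings_count(3)$distinct_mr_upper_bound, "3")
  expect_equal(orderings_count(2)$total, "2")
  expect_equal(orderings_count(2)$distinct_mr_upper_bound, "1")

  oc <- orderings_count(23)
  expect_equal(oc$total, "25852016738884976640000")
  # 23! carries exactly four trailing zeros (factors of five: 4)
  expect_match(oc$total, "[1-9]0000$")
  expect_equal(signif(as.numeric(oc$total), 3), 2.59e22)
  # doubling the distinct-orderings bound recovers n!
  expect_equal(2 * as.numeric(oc$distinct_mr_upper_bound), as.numeric(oc$total))
  expect_error(orderings_count(1), "insufficient")
})

test_that("the report is internally consistent and recommends by ordering", {
  obs <- generate_compliance_data(n = 23, seed = 5)
  rep <- build_report(obs)
  expect_s3_class(rep, "ambiguity_report")
  expect_equal(rep$width_difference, rep$width_max - rep$width_min)
  expect_equal(
    rep$width_difference_over_range,
    rep$width_difference / (rep$data_summary$max - rep$data_summary$min)
  )
  expect_equal(rep$width_min, 2 * 2.66 * rep$extremal$mr_bar_min)
  expect_equal(rep$width_max, 2 * 2.66 * rep$extremal$mr_bar_max)
  expect_gte(rep$width_difference, 0)
  expect_equal(rep$recommendation, "use_outlier_methods")
  expect_true(rep$skew_advisory) # generator default is right-skewed

  counts <- rep$flagged_counts
  expect_lte(
    counts$flagged[counts$scheme == "xmr_max_limits"],
    counts$flagged[counts$scheme == "xmr_min_limits"]
  )
  expect_lte(
    counts$flagged[counts$scheme == "outer_fences"],
    counts$flagged[counts$scheme == "inner_fences"]
  )

  ordered <- observation_set(obs$value, obs$label, ordered = TRUE)
  expect_equal(build_report(ordered)$recommendation, "use_xmr")
})

test_that("constant data produces a degenerate but valid report", {
  rep <- build_report(observation_set(rep(40, 6)))
  expect_equal(rep$width_min, 0)
  expect_equal(rep$width_max, 0)
  expect_true(is.na(rep$width_difference_over_range))
  expect_equal(sum(rep$flagged_counts$flagged), 0)
})

test_that("adding an extreme datum never decreases the maximal width", {
  for (seed in 1:10) {
    x <- random_dataset(9, 60 + seed)
    base <- build_report(observation_set(x))$width_max
    grown <- build_report(observation_set(c(x, max(x) + 50)))$width_max
    expect_gte(grown, base)
  }
})

test_that("JSON reports round-trip losslessly", {
  obs <- generate_compliance_data(n = 10, seed = 2)
  rep <- build_report(obs, resamples = 50, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path, format = "json")
  back <- read_report(path)
  expect_equal(back$width_difference, rep$width_difference)
  expect_equal(back$extremal$s_max, rep$extremal$s_max)
  expect_equal(back$extremal$mr_bar_min, rep$extremal$mr_bar_min)
  expect_equal(back$orderings_total, rep$orderings_total)
  expect_equal(back$flagged_counts, rep$flagged_counts)
  expect_equal(back$resample$mr_values, rep$resample$mr_values)
  expect_equal(back$recommendation, rep$recommendation)
})

test_that("csv and text report formats follow their schemas", {
  rep <- build_report(generate_compliance_data(n = 8, seed = 3))
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, csv_path, format = "csv")
  tab <- readr::read_csv(csv_path, show_col_types = FALSE)
  expect_equal(names(tab), c("statistic", "value"))
  expect_true(all(c("mr_bar_min", "mr_bar_max", "width_difference") %in% tab$statistic))
  # full precision in csv/json; display rounding only in text
  expect_equal(
    tab$value[tab$statistic == "mr_bar_max"], rep$extremal$mr_bar_max
  )

  txt_path <- withr::local_tempfile(fileext = ".txt")
  write_report(rep, txt_path, format = "text")
  txt <- readLines(txt_path)
  expect_true(any(grepl(
    format_sig(rep$extremal$mr_bar_max), txt,
    fixed = TRUE
  )))
})

test_that("chart export writes one row per observation with all bounds", {
  obs <- generate_compliance_data(n = 23, seed = 7)
  rep <- build_report(obs)
  path <- withr::local_tempfile(fileext = ".csv")
  exported <- chart_export(obs, rep, path)
  expect_equal(nrow(exported), 23)
  expect_equal(exported$xmr_min_lower, rep(rep$limits_min$lower, 23))
  expect_equal(exported$xmr_max_upper, rep(rep$limits_max$upper, 23))
  on_disk <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(on_disk), 23)
  # bounds outside [0, 100] are marked clipped for percentage data
  if (rep$limits_max$lower < 0) {
    expect_true(all(on_disk$clipped_xmr_max_lower))
  }
  p <- autoplot(rep, obs)
  expect_s3_class(p, "ggplot")
})
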