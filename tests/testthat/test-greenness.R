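test_that("eco-scale scoring and classification follow the penalty rules", {
  sheet <- eco_scale(eco_items_voltammetric())
  expect_equal(sheet$total_pp, 10)
  expect_equal(sheet$score, 90)
  expect_equal(sheet$classification, "great green")

  hplc <- eco_scale(eco_items_hplc())
  expect_equal(hplc$score, 77)
  expect_equal(hplc$classification, "great green")

  expect_equal(eco_scale(NULL)$score, 100)
  expect_equal(eco_scale(NULL)$classification, "ideal")

  mid <- eco_scale(data.frame(label = "x", category = "waste", penalty = 40))
  expect_equal(mid$classification, "acceptable")
  expect_warning(
    low <- eco_scale(data.frame(label = "x", category = "waste",
                                penalty = 120)),
    "floored")
  expect_equal(low$score, 0)

  # score + penalties = 100 whenever no flooring occurs
  expect_equal(sheet$score + sheet$total_pp, 100)

  expect_error(eco_scale(data.frame(label = "x", category = "vibes",
                                    penalty = 1)), "unknown")
})

test_that("pooled t statistics reproduce the two-method comparison", {
  # summaries built from mean/SD; the printed variances are 2-decimal
  # roundings of SD^2 and reproduce the printed t only through the SDs
  volt <- list(LD = method_summary(99.76, 0.79, n = 5),
               CD = method_summary(100.69, 1.13, n = 5),
               ENT = method_summary(99.50, 0.52, n = 5))
  hplc <- list(LD = method_summary(100.13, 0.65, n = 5),
               CD = method_summary(100.78, 0.71, n = 5),
               ENT = method_summary(99.63, 0.47, n = 5))
  t_printed <- c(LD = -0.81, CD = -0.15, ENT = -0.41)
  for (a in names(volt)) {
    tt <- pooled_t_test(volt[[a]], hplc[[a]], t_critical = 2.132)
    expect_equal(round(tt$t, 2), t_printed[[a]])
    expect_equal(tt$df, 8L)
    expect_equal(tt$verdict, "no significant difference")
  }

  # identical summaries: t = 0; swapping the methods flips the sign
  s <- method_summary(100, 1, n = 5)
  expect_equal(pooled_t_test(s, s)$t, 0)
  ab <- pooled_t_test(volt$LD, hplc$LD)$t
  ba <- pooled_t_test(hplc$LD, volt$LD)$t
  expect_equal(ab, -ba, tolerance = 1e-12)
})

test_that("summary-based t equals the raw-data computation", {
  a_raw <- c(99.2, 100.4, 101.1)
  b_raw <- c(98.9, 99.8, 100.0)
  a <- method_summary(mean(a_raw), sd(a_raw), n = 3)
  b <- method_summary(mean(b_raw), sd(b_raw), n = 3)
  oracle <- t.test(a_raw, b_raw, var.equal = TRUE)
  expect_equal(pooled_t_test(a, b)$t, unname(oracle$statistic),
               tolerance = 1e-12)
})

test_that("variance-ratio tests reproduce the printed F values", {
  f_printed <- c(1.48, 2.51, 1.23)
  va <- list(c(0.62, 0.42), c(1.28, 0.51), c(0.27, 0.22))
  for (i in 1:3) {
    a <- method_summary(100, variance = va[[i]][1], n = 5)
    b <- method_summary(100, variance = va[[i]][2], n = 5)
    ft <- variance_ratio_test(a, b, f_critical = 6.39)
    expect_equal(round(ft$f, 2), f_printed[i])
    expect_equal(ft$f, va[[i]][1] / va[[i]][2], tolerance = 1e-12)
    expect_equal(ft$verdict, "no significant difference")
    # larger-over-smaller convention: order of arguments is irrelevant
    expect_equal(variance_ratio_test(b, a)$f, ft$f)
    expect_gte(ft$f, 1)
  }
  eq <- method_summary(100, variance = 0.5, n = 5)
  expect_equal(variance_ratio_test(eq, eq)$f, 1)
})

test_that("method summaries cross-check sd against variance", {
  expect_error(method_summary(100, sd = 1, variance = 4, n = 5),
               "inconsistent")
  expect_error(method_summary(100, sd = 1, n = 1), "n must")
  expect_equal(method_summary(100, sd = 2, n = 5)$variance, 4)
})
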