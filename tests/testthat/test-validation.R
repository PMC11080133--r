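test_that("error statistics implement the RMSE and REP definitions", {
  s <- error_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s$rmse, 0)
  expect_equal(s$rep_percent, 0)

  # hand arithmetic oracle
  s <- error_stats(c(1, 2, 3), c(1, 2, 5))
  expect_equal(s$rmse, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(s$y_mean, 8 / 3, tolerance = 1e-12)
  expect_equal(s$rep_percent, 100 * sqrt(4 / 3) / (8 / 3), tolerance = 1e-12)
  expect_equal(round(s$rep_percent, 2), 43.30)

  # identity rep = 100 * rmse / y_mean on random cases
  set.seed(41)
  for (i in 1:10) {
    y <- runif(7, 1, 2); p <- y + rnorm(7, 0, 0.1)
    s <- error_stats(p, y)
    expect_equal(s$rep_percent, 100 * s$rmse / mean(y), tolerance = 1e-12)
  }
})

test_that("printed RMSEP/REP pairs are mutually consistent with the linear range", {
  # after-SG levodopa prediction errors: RMSEP 1.98e-6 at REP 0.48 %
  # imply a mean nominal level inside levodopa's linear range
  y_mean <- 100 * 1.98e-6 / 0.48
  rng <- default_analyte_specs()$LD$linear_range
  expect_gt(y_mean, rng[1])
  expect_lt(y_mean, rng[2])
})

test_that("CV-ANOVA tables reproduce printed F statistics from SS and DF", {
  # levodopa block: SS 10.54 / DF 20 vs SS 13.46 / DF 4
  t1 <- cv_anova_from_ss(10.54, 20, 13.46, 4)
  expect_equal(round(t1$MS[2], 3), 0.527)
  expect_equal(round(t1$F[2], 3), 0.157)
  expect_equal(round(t1$p[2], 3), 0.998)
  expect_equal(round(t1$SD[2], 3), 0.726)
  expect_equal(round(t1$SD[3], 2), 1.83)

  # entacapone block: SS 16.29 / DF 20 vs SS 7.71 / DF 4
  t2 <- cv_anova_from_ss(16.29, 20, 7.71, 4)
  expect_equal(round(t2$F[2], 3), 0.423)
  expect_equal(t2$p[2], 0.912, tolerance = 2e-3)

  # additivity invariants hold exactly
  expect_equal(t1$SS[1], t1$SS[2] + t1$SS[3])
  expect_equal(t1$DF[1], t1$DF[2] + t1$DF[3])
  expect_equal(t1$MS, t1$SS / t1$DF)

  # p-value equals numeric integration of the F density
  p_num <- integrate(function(x) df(x, 20, 4), t1$F[2], Inf,
                     rel.tol = 1e-10)$value
  expect_equal(t1$p[2], p_num, tolerance = 1e-6)
})

test_that("cv_anova assembles the table from scaled responses and residuals", {
  set.seed(42)
  y <- rnorm(25); y <- (y - mean(y)) / sd(y)
  res <- rnorm(25, 0, 0.3)
  tab <- cv_anova(y, res, df_regression = 20)
  expect_equal(tab$SS[1], sum((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(tab$SS[3], sum(res^2), tolerance = 1e-12)
  expect_equal(tab$DF, c(24, 20, 4))
  expect_equal(tab$F[2], (tab$SS[2] / 20) / (tab$SS[3] / 4),
               tolerance = 1e-12)
})

test_that("permutation testing separates real models from chance", {
  conc <- design_conc()
  gen <- synth_set(artifact_spec(baseline_kind = "none", baseline_scale = 0,
                                 jitter_sd = 0, noise_sd = 1e-8, seed = 51))
  X <- gen$set$matrix[1:16, ]
  y <- conc$values[1:16, "LD"]
  pt <- permutation_test(X, y, n_lv = 3, n_perm = 15, seed = 1)
  expect_true(all(pt$perms$r2 <= 1 + 1e-8))
  expect_gt(pt$original["q2"], max(pt$perms$q2))
  expect_lt(pt$q2_intercept, 0)

  # identity permutation reproduces the original statistics exactly
  st <- voltachemo:::r2_q2(X, y, 3)
  expect_equal(unname(st["r2"]), unname(pt$original["r2"]), tolerance = 1e-12)
})

test_that("leverages are projector diagonals", {
  set.seed(52)
  X <- matrix(rnorm(12 * 10), 12)
  Y <- matrix(rnorm(24), 12)
  fit <- pls_fit(X, Y, n_lv = 3)
  lev <- leverages(fit)
  expect_equal(sum(lev$leverage_x), 3, tolerance = 1e-10)
  expect_true(all(lev$leverage_x >= -1e-12 & lev$leverage_x <= 1 + 1e-12))
  expect_true(all(lev$leverage_y >= -1e-12 & lev$leverage_y <= 1 + 1e-12))

  # 4 x 2 toy score matrix against explicit dense algebra
  S <- matrix(c(1, 2, -1, 0.5, 0.3, -2, 1.5, 0.2), 4, 2)
  H <- S %*% solve(t(S) %*% S) %*% t(S)
  toy <- fit
  toy$T <- S; toy$U <- S
  expect_equal(leverages(toy)$leverage_x, diag(H), tolerance = 1e-12)
})

test_that("Hotelling T2 follows the score-variance form and F threshold", {
  set.seed(53)
  X <- matrix(rnorm(20 * 15), 20)
  Y <- matrix(rnorm(40), 20)
  fit <- pls_fit(X, Y, n_lv = 2)
  ht <- hotelling_t2(fit, alpha = 0.05)
  N <- 20; A <- 2
  # algebraic oracle: mean T2 over samples for centred scores
  expect_equal(mean(ht$t2), A * (N - 1) / N, tolerance = 1e-10)
  expect_equal(ht$critical,
               A * (N - 1) * (N + 1) / (N * (N - A)) * qf(0.95, A, N - A),
               tolerance = 1e-12)
  expect_true(all(ht$t2 >= 0))
})

test_that("standardized residuals flag only genuine outliers", {
  # alternating unit residuals: all |z| exactly 1, nothing flagged
  sr <- standardized_residuals(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(abs(sr$z), rep(1, 4), tolerance = 1e-12)
  expect_false(any(sr$flags))

  # perfect fit: no flags
  sr <- standardized_residuals(1:5, 1:5)
  expect_false(any(sr$flags))
  expect_equal(sr$z, rep(0, 5))

  # one gross outlier among 20 small residuals is the only flag
  set.seed(54)
  y <- rnorm(20)
  p <- y + rnorm(20, 0, 0.05)
  p[7] <- y[7] + 5
  sr <- standardized_residuals(p, y)
  expect_equal(which(sr$flags), 7L)
  expect_equal(nrow(sr$npp), 20L)
})
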