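test_that("the five-level three-factor design is balanced and orthogonal", {
  d <- brereton_design(5, 3)
  expect_equal(d$n_runs, 25L)
  expect_equal(nrow(d$level_codes), 25L)

  # every code appears exactly five times in every factor column
  for (j in 1:3) {
    expect_equal(unname(table(d$level_codes[, j])), rep(5L, 5),
                 ignore_attr = TRUE)
  }
  # pairwise column correlations are exactly zero
  cors <- cor(d$level_codes)
  expect_equal(max(abs(cors[upper.tri(cors)])), 0, tolerance = 1e-12)

  # regeneration is deterministic
  expect_identical(brereton_design(5, 3), d)
})

test_that("other supported level counts keep the design invariants", {
  for (q in c(2L, 3L, 4L, 7L)) {
    d <- brereton_design(q, min(q, 3L))
    expect_equal(d$n_runs, q^2)
    for (j in seq_len(d$n_factors)) {
      expect_equal(unname(table(d$level_codes[, j])), rep(q, q),
                   ignore_attr = TRUE)
    }
    if (d$n_factors > 1) {
      cors <- cor(d$level_codes)
      expect_equal(max(abs(cors[upper.tri(cors)])), 0, tolerance = 1e-12)
    }
  }
  expect_error(brereton_design(6, 3), "unsupported")
  expect_error(brereton_design(5, 6), "n_factors")
})

test_that("level codes map affinely onto the analyte linear ranges", {
  d <- brereton_design(5, 3)
  specs <- default_analyte_specs()
  ranges <- lapply(specs, function(s) s$linear_range)
  tab <- map_levels_to_concentrations(d, ranges)

  # extreme codes hit the range ends
  ld <- tab$values[, "LD"]
  expect_equal(min(ld), 4.00e-5)
  expect_equal(max(ld), 9.00e-4)

  # equal spacing between consecutive levels
  lv <- sort(unique(ld))
  expect_equal(diff(lv) / diff(lv)[1], rep(1, 4), tolerance = 1e-12)

  # ENT code -1 by independent linear interpolation
  ent <- sort(unique(tab$values[, "ENT"]))
  expect_equal(ent[2], 3.20e-6 + 0.25 * (4.00e-4 - 3.20e-6),
               tolerance = 1e-12)

  expect_error(map_levels_to_concentrations(d, list(c(1, 0), c(0, 1), c(0, 1))),
               "inverted")
})

test_that("the seeded 16/9 split is deterministic, disjoint and level-covering", {
  tab <- design_conc()
  s1 <- split_calibration_validation(tab, 16, 9, seed = 1)
  s2 <- split_calibration_validation(tab, 16, 9, seed = 1)
  expect_identical(s1, s2)
  expect_length(s1$cal, 16)
  expect_length(s1$val, 9)
  expect_length(intersect(s1$cal, s1$val), 0)

  # exhaustive level tally: every factor level present in both subsets
  lev <- apply(tab$values, 2, function(v) match(v, sort(unique(v))))
  for (ids in list(s1$cal, s1$val)) {
    rows <- match(ids, tab$samples)
    for (j in 1:3) expect_setequal(unique(lev[rows, j]), 1:5)
  }
  expect_true(s1$balanced)

  expect_error(split_calibration_validation(tab, 20, 9), "exceed")
})

test_that("univariate fits recover exact lines and the generator truth", {
  # exact line
  x <- c(1, 2, 3, 4, 5)
  f <- univariate_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)

  # normal-equation oracle on 5 hand points
  set.seed(12)
  y <- 3 * x - 2 + rnorm(5)
  f <- univariate_fit(x, y)
  b <- solve(cbind(1, x) |> crossprod(), crossprod(cbind(1, x), y))
  expect_equal(c(f$intercept, f$slope), as.numeric(b), tolerance = 1e-12)

  # noiseless single-analyte voltammograms recover Table-style parameters
  spec <- default_analyte_specs()$LD
  concs <- seq(spec$linear_range[1], spec$linear_range[2], length.out = 8)
  tab <- conc_table(matrix(concs, ncol = 1), analytes = "LD")
  gen <- generate_mixture_set(tab, list(LD = spec), no_artifacts())
  apex <- peak_current(gen$set, ep = 0.29)
  f <- univariate_fit(concs, apex)
  expect_equal(f$slope, 0.0681, tolerance = 1e-9)
  expect_equal(f$intercept, -2.76e-7, tolerance = 1e-6)
  expect_equal(f$r, 1, tolerance = 1e-9)

  expect_error(univariate_fit(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("with noise the univariate slope is unbiased across seeds", {
  spec <- default_analyte_specs()$ENT
  concs <- seq(spec$linear_range[1], spec$linear_range[2], length.out = 8)
  tab <- conc_table(matrix(concs, ncol = 1), analytes = "ENT")
  slopes <- vapply(1:40, function(seed) {
    gen <- generate_mixture_set(
      tab, list(ENT = spec),
      artifact_spec(baseline_kind = "none", baseline_scale = 0,
                    jitter_sd = 0, noise_sd = 2e-7, seed = seed))
    univariate_fit(concs, peak_current(gen$set, 0.46))$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.0611), 2 * se + 1e-4)
})
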