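test_that("NIPALS reproduces exact low-rank and full-rank systems", {
  set.seed(21)
  # rank-1: one latent variable suffices
  t1 <- rnorm(10)
  X <- t1 %*% t(rnorm(6))
  y <- 2 * t1
  fit <- pls_fit(X, y, n_lv = 1, x_scaling = "center", y_scaling = "center")
  expect_lt(max(abs(fit$fitted - y)), 1e-8)

  # full rank: PLS with all components equals least squares (pinv oracle)
  X <- matrix(rnorm(40), 8, 5)
  Y <- matrix(rnorm(16), 8, 2)
  fit <- pls_fit(X, Y, n_lv = 5, x_scaling = "center", y_scaling = "center")
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  B_ls <- if (requireNamespace("pracma", quietly = TRUE))
    pracma::pinv(Xc) %*% Yc else solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_equal(unname(fit$B), unname(B_ls), tolerance = 1e-6)

  expect_error(pls_fit(X, cbind(Y[, 1], 3), n_lv = 2), "zero-variance")
})

test_that("score vectors are mutually orthogonal", {
  set.seed(22)
  X <- matrix(rnorm(20 * 30), 20)
  Y <- matrix(rnorm(40), 20)
  fit <- pls_fit(X, Y, n_lv = 5)
  G <- crossprod(fit$T)
  off <- max(abs(G[upper.tri(G)]))
  expect_lt(off, 1e-8 * sum(diag(G)))
  expect_equal(colSums(fit$W^2), rep(1, 5), tolerance = 1e-10)
})

test_that("prediction is consistent, deterministic and unit-invariant", {
  set.seed(23)
  X <- matrix(rnorm(12 * 20), 12)
  Y <- matrix(rnorm(24), 12)
  fit <- pls_fit(X, Y, n_lv = 3)

  expect_equal(pls_predict(fit, X), fit$fitted)
  expect_equal(pls_predict(fit, X[c(1, 1), ])[1, ],
               pls_predict(fit, X[c(1, 1), ])[2, ])
  expect_error(pls_predict(fit, X[, 1:5]), "column count")

  # scaling a response column by 1000 rescales predictions exactly
  Y2 <- Y; Y2[, 2] <- Y2[, 2] * 1000
  fit2 <- pls_fit(X, Y2, n_lv = 3)
  expect_equal(pls_predict(fit2, X)[, 2] / 1000, pls_predict(fit, X)[, 2],
               tolerance = 1e-10)
})

test_that("noiseless ternary mixtures are predicted to 0.1 percent", {
  conc <- design_conc()
  gen <- synth_set(no_artifacts())
  fit <- pls_fit(gen$set$matrix[1:16, ], conc$values[1:16, ], n_lv = 3)
  pred <- pls_predict(fit, gen$set$matrix[17:25, ])
  expect_lt(max(abs(pred - conc$values[17:25, ]) / conc$values[17:25, ]),
            1e-3)
})

test_that("cross-validation matches an explicit leave-one-out loop", {
  set.seed(24)
  X <- matrix(rnorm(6 * 8), 6)
  Y <- matrix(rnorm(12), 6)
  cv <- cross_validate(X, Y, max_lv = 2, scheme = "loo",
                       x_scaling = "center", y_scaling = "center")
  # hand-rolled oracle
  for (a in 1:2) {
    pred <- matrix(NA, 6, 2)
    for (i in 1:6) {
      f <- pls_fit(X[-i, ], Y[-i, ], n_lv = a,
                   x_scaling = "center", y_scaling = "center")
      pred[i, ] <- pls_predict(f, X[i, , drop = FALSE])
    }
    expect_equal(unname(cv$rmsecv[a, ]), sqrt(colMeans((pred - Y)^2)),
                 tolerance = 1e-10)
  }
  expect_true(all(is.finite(cv$rmsecv)) && all(cv$rmsecv >= 0))
  expect_equal(cv$press, 6 * cv$rmsecv^2)
})

test_that("RMSECV falls with model rank on three-component data", {
  conc <- design_conc()
  gen <- synth_set(artifact_spec(baseline_kind = "none", baseline_scale = 0,
                                 jitter_sd = 0, noise_sd = 2e-8, seed = 31))
  cv <- cross_validate(gen$set$matrix[1:16, ], conc$values[1:16, ],
                       max_lv = 3)
  # pooled error falls monotonically to the data rank, and every analyte
  # ends far below where it started
  pooled <- sqrt(rowMeans(cv$rmsecv^2))
  expect_true(all(diff(pooled) < 0))
  for (j in 1:3) expect_lt(cv$rmsecv[3, j], 0.1 * cv$rmsecv[1, j])
})

test_that("the parsimony rule picks the smallest adequate LV count", {
  expect_equal(select_n_lv(c(1, 1, 1)), 1L)
  expect_equal(select_n_lv(c(10, 4, 1, 0.99, 0.985), tol = 0.02), 3L)

  # noiseless rank-3 mixtures select exactly three latent variables
  conc <- design_conc()
  gen <- synth_set(no_artifacts())
  cv <- cross_validate(gen$set$matrix[1:16, ], conc$values[1:16, ],
                       max_lv = 5)
  expect_equal(select_n_lv(cv), 3L)
})
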