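test_that("alignment targets are computed as specified", {
  g <- potential_grid(0, 0.04, 0.01)
  m <- matrix(rnorm(15), 3, 5)
  s <- voltammogram_set(g, m)
  expect_equal(build_target(s, "average")$current, colMeans(m))

  two <- voltammogram_set(g, rbind(m[1, ], m[1, ]))
  expect_equal(build_target(two, "average")$current, m[1, ])

  pm <- voltammogram_set(g, rbind(m[1, ], -m[1, ]))
  expect_equal(build_target(pm, "average")$current, rep(0, 5))

  expect_error(build_target(voltammogram_set(g, matrix(numeric(0), 0, 5))),
               "empty")
})

test_that("interval alignment finds the constructed shift", {
  set.seed(11)
  seg <- exp(-(seq_len(40) - 18)^2 / 20)
  # target delayed by +3 points: segment must move rightward by 3
  target <- c(rep(seg[1], 3), seg[1:37])
  al <- align_interval(seg, target, max_shift = 10)
  expect_equal(al$shift, 3L)
  expect_equal(al$aligned, target, tolerance = 1e-12)

  expect_equal(align_interval(seg, seg, 10)$shift, 0L)
  expect_error(align_interval(1, 1, 3), "2 points")
})

test_that("interval alignment agrees with an exhaustive brute-force search", {
  brute <- function(seg, tgt, ms) {
    tc <- tgt - mean(tgt)
    cand <- seq.int(-ms, ms)
    cand <- cand[order(abs(cand), cand)]
    vals <- sapply(cand, function(s) {
      sh <- voltachemo:::shift_segment(seg, s, "edge")
      sum(tc * (sh - mean(sh)))
    })
    cand[which.max(vals)]
  }
  for (seed in 1:20) {
    set.seed(seed)
    seg <- rnorm(20)
    tgt <- rnorm(20)
    expect_equal(align_interval(seg, tgt, 6)$shift, brute(seg, tgt, 6))
  }
})

test_that("whole-trace alignment recovers injected jitter exactly", {
  # constant-composition replicates: the pure ground-truth case, free of
  # the one-point ambiguity that composition contrast can introduce
  specs <- default_analyte_specs()
  conc <- conc_table(matrix(rep(c(4e-4, 2.5e-4, 2e-4), each = 25), 25),
                     analytes = names(specs))
  jit <- rep_len(c(-3L, 0L, 3L, -2L, 2L), 25)
  gen <- generate_mixture_set(
    conc, specs,
    artifact_spec(baseline_kind = "none", baseline_scale = 0,
                  jitter_sd = 0, noise_sd = 0, jitter_steps = jit))
  al <- icoshift_align(gen$set)
  expect_equal(ncol(al$shifts), 1L)       # 800 > 261: one interval
  expect_equal(as.vector(al$shifts), -jit)
  expect_equal(dim(al$set$matrix), dim(gen$set$matrix))

  # realigning the aligned set is a no-op
  al2 <- icoshift_align(al$set)
  expect_true(all(al2$shifts == 0L))
  expect_equal(al2$set$matrix, al$set$matrix)
})

test_that("ternary mixtures align to a common offset up to rare flips", {
  # with strongly varying composition the cross-correlation top is nearly
  # flat, so a few samples may settle one point off the consensus; the
  # bulk must still land on one common offset
  conc <- design_conc()
  jit <- rep_len(c(-3L, 0L, 3L, -2L, 2L), 25)
  gen <- synth_set(artifact_spec(baseline_kind = "none", baseline_scale = 0,
                                 jitter_sd = 0, noise_sd = 0,
                                 jitter_steps = jit))
  al <- icoshift_align(gen$set)
  resid <- jit + as.vector(al$shifts)
  mode_off <- as.integer(names(which.max(table(resid))))
  expect_gte(sum(resid == mode_off), 20)
  expect_lte(max(abs(resid - mode_off)), 1)
})

test_that("aligning a set of identical rows yields zero shifts", {
  g <- potential_grid()
  row <- exp(-(g$potentials - 0.5)^2 / 0.004)
  s <- voltammogram_set(g, matrix(row, 3, length(row), byrow = TRUE))
  al <- icoshift_align(s)
  expect_true(all(al$shifts == 0L))
  expect_equal(al$set$matrix, s$matrix)
})

test_that("interval splitting follows the width rule", {
  g <- potential_grid(0, 0.099, 0.001)   # 100 points
  set.seed(2)
  s <- voltammogram_set(g, matrix(rnorm(300), 3))
  al <- icoshift_align(s, icoshift_params(interval_width = 30, passes = 1))
  expect_equal(ncol(al$shifts), 4L)      # 30+30+30+10
  expect_equal(dim(al$set$matrix), dim(s$matrix))
})

test_that("alignment never reduces the summed correlation with the target", {
  conc <- design_conc()
  gen <- synth_set(artifact_spec(baseline_kind = "none", baseline_scale = 0,
                                 jitter_sd = 0.01, noise_sd = 0, seed = 3))
  tgt <- build_target(gen$set, "average")
  al <- icoshift_align(gen$set, icoshift_params(passes = 1))
  score <- function(m) sum(apply(m, 1, function(r)
    sum((tgt$current - mean(tgt$current)) * (r - mean(r)))))
  expect_gte(score(al$set$matrix), score(gen$set$matrix))
})
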