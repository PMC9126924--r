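test_that("a pure tone sifts into a single dominant IMF", {
  x <- sin(2 * pi * (0:255) / 32)
  d <- sift(x)
  expect_s3_class(d, "imf_decomposition")
  expect_gt(abs(cor(d$imfs[, 1], x)), 0.99)
  expect_lt(max(abs(d$residual)), 0.01 * diff(range(x)))
})

test_that("a two-tone mixture separates into its components", {
  t <- 0:511
  hi <- sin(2 * pi * t / 8)
  lo <- sin(2 * pi * t / 64)
  d <- sift(hi + lo)
  expect_gte(n_imfs(d), 2)
  expect_gt(abs(cor(d$imfs[, 1], hi)), 0.95)
  expect_gt(abs(cor(d$imfs[, 2], lo)), 0.95)
})

test_that("sifting is complete and IMFs satisfy the extrema/zero-crossing property", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      n <- sample(64:256, 1)
      x <- as.numeric(stats::arima.sim(list(ar = 0.6), n)) +
        sin(2 * pi * seq_len(n) / sample(8:32, 1))
      d <- sift(x)
      expect_lt(max(abs(x - reconstruct(d))), 1e-10 * diff(range(x)))
    }
  })
  # IMF property spot check, away from the boundaries
  x <- withr::with_seed(1, cumsum(rnorm(256)))
  d <- sift(x)
  for (j in seq_len(n_imfs(d))) {
    imf <- d$imfs[3:254, j]
    n_ext <- sum(diff(sign(diff(imf))) != 0)
    n_zc <- sum(abs(diff(sign(imf))) == 2)
    expect_lte(abs(n_ext - n_zc), 1)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(sift(rep(1, 100)), "constant")
  expect_error(sift(c(1, 2, 3)), "too short")
  expect_error(sift(c(rep(0, 50), NA, rep(1, 49))), "non-finite")
})

test_that("eemd with no noise and a single member equals plain sifting", {
  x <- withr::with_seed(3, rnorm(128)) + sin(2 * pi * (1:128) / 16)
  p <- eemd_params(noise_level = 0, n_ensemble = 1)
  expect_identical(eemd(x, p)$imfs, sift(x, p)$imfs)
})

test_that("eemd is seed-deterministic and at least as good as sift on tones", {
  t <- 0:511
  hi <- sin(2 * pi * t / 8); lo <- sin(2 * pi * t / 64)
  x <- hi + lo
  p <- eemd_params(noise_level = 0.085, n_ensemble = 100, seed = 5)
  d1 <- eemd(x, p)
  d2 <- eemd(x, p)
  expect_identical(d1$imfs, d2$imfs)
  ds <- sift(x)
  expect_gte(abs(cor(d1$imfs[, 1], hi)), abs(cor(ds$imfs[, 1], hi)) - 0.02)
  expect_gte(abs(cor(d1$imfs[, 2], lo)), abs(cor(ds$imfs[, 2], lo)) - 0.02)
})

test_that("orthogonality index matches closed forms and is scale invariant", {
  n <- 256; t <- 0:(n - 1)
  a <- sin(2 * pi * t * 8 / n)
  b <- sin(2 * pi * t * 3 / n)     # integer cycles: exactly orthogonal
  d_orth <- imf_decomposition(cbind(a, b), rep(0, n))
  expect_lt(orthogonality_index(d_orth), 1e-10)
  d_same <- imf_decomposition(cbind(a, a), rep(0, n))
  expect_equal(orthogonality_index(d_same), 0.25, tolerance = 1e-12)
  d_single <- imf_decomposition(cbind(a), rep(0, n))
  expect_equal(orthogonality_index(d_single), 0)
  x <- withr::with_seed(9, rnorm(128) + sin(2 * pi * (1:128) / 16))
  d1 <- sift(x); d10 <- sift(10 * x)
  expect_equal(orthogonality_index(d1), orthogonality_index(d10),
               tolerance = 1e-8)
})

test_that("separability distinguishes disjoint from entangled bands", {
  n <- 256; t <- 0:(n - 1)
  fast <- sin(2 * pi * t * 32 / n)
  slow <- sin(2 * pi * t * 4 / n)
  d <- imf_decomposition(cbind(fast, slow), rep(0, n))
  expect_gt(separability_index(d, d), 0.9)
  d1 <- imf_decomposition(cbind(fast), rep(0, n))
  expect_equal(separability_index(d1, d1), 1)
  mix <- sift(fast + slow)
  expect_gt(separability_index(mix, mix), 0.5)
})

test_that("noise-level selection is deterministic, order-invariant, and flags failures", {
  x <- sin(2 * pi * (0:199) / 10) + withr::with_seed(2, rnorm(200, sd = 0.3))
  y <- sin(2 * pi * (0:199) / 10 + 1) + withr::with_seed(4, rnorm(200, sd = 0.3))
  expect_equal(as.numeric(select_noise_level(x, y, 0.085,
                                             eemd_params(n_ensemble = 10))),
               0.085)
  p <- eemd_params(n_ensemble = 10)
  r_fwd <- select_noise_level(x, y, c(0, 0.085), p)
  r_rev <- select_noise_level(x, y, c(0.085, 0), p)
  expect_equal(as.numeric(r_fwd), as.numeric(r_rev))
  r_flag <- select_noise_level(x, y, c(0, 0.085), p,
                               orthogonality_threshold = 1e-12)
  expect_true(attr(r_flag, "flagged"))
})
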