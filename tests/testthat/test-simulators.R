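test_that("Moran model returns the requested tail with the expected layout", {
  ms <- simulate_moran(moran_params(seed = 1))
  expect_s3_class(ms, "multi_series")
  expect_equal(dim(ms), c(200L, 5L))
  expect_equal(colnames(ms), c("N1", "N2", "R1", "R2", "V"))
  expect_true(all(is.finite(ms)))
  expect_true(all(ms[, c("N1", "N2")] > 0))
})

test_that("Moran model is deterministic under a fixed seed", {
  a <- simulate_moran(moran_params(seed = 7))
  b <- simulate_moran(moran_params(seed = 7))
  expect_identical(unclass(a), unclass(b))
  c <- simulate_moran(moran_params(seed = 8))
  expect_false(identical(unclass(a), unclass(c)))
})

test_that("shared forcing induces a significant N1-N2 correlation", {
  for (s in 1:3) {
    ms <- simulate_moran(moran_params(seed = s))
    ct <- pearson_significance(ms[, "N1"], ms[, "N2"])
    expect_lt(ct$p, 0.05)
    expect_gt(ct$r, 0)
  }
})

test_that("decoupling the forcing destroys the correlation at the nominal rate", {
  # with psi1 = psi2 = 0 the populations are fully independent chaotic
  # maps, so significance should occur at about the alpha = 0.05 rate
  n_rep <- 500
  sig <- vapply(seq_len(n_rep), function(s) {
    ms <- simulate_moran(moran_params(psi1 = 0, psi2 = 0, seed = s,
                                      n_steps = 2000, n_keep = 200))
    pearson_significance(ms[, "N1"], ms[, "N2"])$p < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(mean(sig), 0.05 + 3 * se)
})

test_that("Moran parameter validation rejects impossible settings", {
  expect_error(moran_params(n_steps = 100, n_keep = 200), "n_keep")
  expect_error(moran_params(s1 = 1), "retention")
  expect_error(moran_params(D1 = -1), "delays")
  expect_error(moran_params(N1_0 = 0), "positive")
})

test_that("Moran divergence is reported with the failing step", {
  expect_error(simulate_moran(moran_params(psi1 = 600, n_steps = 500,
                                           n_keep = 100)),
               "non-finite at step")
})

test_that("Lotka-Volterra trajectories oscillate and conserve the invariant", {
  p <- lv_params()
  ms <- simulate_lotka_volterra(p)
  expect_equal(colnames(ms), c("x", "y"))
  expect_true(all(ms > 0))
  x <- ms[, "x"]
  expect_gte(length(find_local_maxima_for_test(x)), 3)
  # invariant drift over the whole run, relative to its initial value
  H <- lv_invariant(ms[, "x"], ms[, "y"], p)
  expect_lt(max(abs(H - H[1])) / abs(H[1]), 0.001)
})

test_that("halving the integrator step shrinks the invariant drift (RK4 contract)", {
  drift <- function(dt) {
    p <- lv_params(dt = dt, t_end = 20, sample_every = 1)
    ms <- simulate_lotka_volterra(p)
    H <- lv_invariant(ms[, "x"], ms[, "y"], p)
    max(abs(H - H[1]))
  }
  expect_gt(drift(0.02) / drift(0.01), 8)
})

test_that("Lotka-Volterra fixed point stays fixed", {
  p <- lv_params(x0 = 1 / 0.5, y0 = 1 / 0.5, t_end = 20)  # (gamma/delta, alpha/beta)
  ms <- simulate_lotka_volterra(p)
  expect_lt(diff(range(ms[, "x"])), 1e-8)
  expect_lt(diff(range(ms[, "y"])), 1e-8)
})

test_that("prey spectrum has a dominant non-zero peak", {
  ms <- simulate_lotka_volterra()
  pk <- dominant_peak_for_test(ms[, "x"])
  expect_gt(pk$freq, 0)
  # the peak clearly dominates the spectral background
  pg <- stats::spec.pgram(ms[, "x"] - mean(ms[, "x"]), taper = 0,
                          detrend = FALSE, plot = FALSE)
  expect_gt(pk$power / stats::median(pg$spec), 100)
})

test_that("unstable LV integration fails loudly", {
  expect_error(simulate_lotka_volterra(lv_params(dt = 3, t_end = 60)),
               "smaller dt")
})

test_that("white-noise pool has the requested shape and unit-normal aggregate", {
  wn <- simulate_white_noise(2000, 10, seed = 3)
  expect_equal(dim(wn), c(10L, 2000L))
  expect_lt(abs(mean(wn)), 0.02)
  expect_lt(abs(stats::sd(as.numeric(wn)) - 1), 0.02)
  expect_identical(unclass(simulate_white_noise(5, 10, seed = 1)),
                   unclass(simulate_white_noise(5, 10, seed = 1)))
  expect_false(identical(simulate_white_noise(5, 10, seed = 1)[1, 1],
                         simulate_white_noise(5, 10, seed = 2)[1, 1]))
})

test_that("coupled logistic map stays in (0,1) and is seed-deterministic", {
  cl <- simulate_coupled_logistic(coupling_yx = 0.1, seed = 5)
  expect_equal(dim(cl), c(200L, 2L))
  expect_true(all(cl > 0 & cl < 1))
  expect_identical(unclass(cl),
                   unclass(simulate_coupled_logistic(coupling_yx = 0.1, seed = 5)))
  expect_error(simulate_coupled_logistic(coupling_yx = 1.5, seed = 1),
               "escaped")
})

test_that("multi-series CSV round trip preserves values and dt", {
  ms <- simulate_lotka_volterra(lv_params(t_end = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_multiseries(ms, path)
  back <- read_multiseries(path)
  expect_equal(unclass(back), unclass(ms), tolerance = 1e-12)
  expect_equal(attr(back, "dt"), attr(ms, "dt"))
})
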