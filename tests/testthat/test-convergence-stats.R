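make_curve <- function(skill, L = seq(2, length.out = length(skill)),
                       n_pred = rep(100L, length(skill))) {
  structure(list(direction = "X_xmap_Y", library_sizes = as.integer(L),
                 skill = skill, skill_sd = rep(0, length(skill)),
                 n_pred = as.integer(n_pred),
                 degenerate = rep(FALSE, length(skill)),
                 params = NULL),
            class = "ccm_curve")
}

test_that("delta_rho is the end-to-end skill difference", {
  expect_equal(delta_rho(make_curve(c(0.1, 0.3, 0.6))), 0.5)
  expect_equal(delta_rho(make_curve(c(0.2, 0.4, 0.2))), 0)
})

test_that("Fisher delta-rho test matches its closed form", {
  expect_equal(as.numeric(fisher_delta_rho_test(0.5, 0.5, 100, 100)), 0.5)
  # frozen from an independent statistics library:
  # z = (atanh(0.9) - atanh(0.1)) / sqrt(1/97 + 1/97)
  p <- fisher_delta_rho_test(0.9, 0.1, 100, 100)
  expect_equal(attr(p, "z"), 9.554067499514105, tolerance = 1e-12)
  expect_equal(as.numeric(p), 6.235092082599961e-22, tolerance = 1e-10)
  # swapping the roles reflects the p-value
  p_swap <- fisher_delta_rho_test(0.1, 0.9, 100, 100)
  expect_equal(as.numeric(p) + as.numeric(p_swap), 1, tolerance = 1e-12)
})

test_that("Fisher test is monotone in rho_max and guards its domain", {
  ps <- vapply(c(0.2, 0.4, 0.6, 0.8),
               function(r) as.numeric(fisher_delta_rho_test(r, 0.1, 50, 50)),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  clamped <- fisher_delta_rho_test(1, 0.2, 50, 50)
  expect_true(attr(clamped, "clamped"))
  expect_true(is.finite(attr(clamped, "z")))
  expect_error(fisher_delta_rho_test(0.5, 0.1, 3, 50), "more than 3")
})

test_that("Kendall trend test reproduces exact enumeration", {
  up <- kendall_trend_test(make_curve(seq(0.1, 0.9, length.out = 9)))
  expect_equal(up$tau, 1)
  expect_equal(up$method, "exact")
  down <- kendall_trend_test(make_curve(seq(0.9, 0.1, length.out = 9)))
  expect_equal(down$tau, -1)
  expect_gt(down$p, 0.999)
  # frozen oracle for the fixed 9-point curve (checked against both an
  # independent statistics library and brute-force pair enumeration)
  fixed <- kendall_trend_test(make_curve(c(0.1, 0.15, 0.12, 0.2, 0.18,
                                           0.25, 0.24, 0.3, 0.31)))
  expect_equal(fixed$tau, 0.8333333333333334, tolerance = 1e-12)
  expect_equal(fixed$p, 0.0004271384479717813, tolerance = 1e-12)
})

test_that("exact Kendall p equals brute-force permutation enumeration", {
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- sample(4:8, 1)
      skill <- round(rnorm(n), 3)
      if (anyDuplicated(skill)) next
      got <- kendall_trend_test(make_curve(skill))
      want <- brute_kendall(seq_len(n), skill)
      expect_equal(got$tau, want$tau, tolerance = 1e-12)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  })
})

test_that("tied skills fall back to the tie-corrected normal approximation", {
  tied <- kendall_trend_test(make_curve(c(0.1, 0.2, 0.2, 0.3, 0.4)))
  expect_equal(tied$method, "normal")
  expect_true(tied$p > 0 && tied$p < 1)
  ct <- suppressWarnings(stats::cor.test(1:5, c(0.1, 0.2, 0.2, 0.3, 0.4),
                                         method = "kendall",
                                         alternative = "greater"))
  expect_equal(tied$tau, unname(ct$estimate), tolerance = 1e-12)
  flat <- kendall_trend_test(make_curve(rep(0.3, 6)))
  expect_equal(flat$method, "degenerate")
  expect_equal(flat$tau, 0)
  expect_equal(flat$p, 1)
})

test_that("the causal verdict is the conjunction of all three indices", {
  rising <- make_curve(c(0.05, 0.3, 0.5, 0.65, 0.75, 0.8), n_pred = rep(150L, 6))
  v <- ccm_verdict(rising, alpha = 0.05)
  expect_equal(v$verdict, "causal")
  flat <- make_curve(c(0.31, 0.3, 0.32, 0.31, 0.3, 0.32), n_pred = rep(150L, 6))
  expect_equal(ccm_verdict(flat)$verdict, "non_causal")
  # significant trend but negative overall improvement is not causal
  falling <- make_curve(c(0.8, 0.75, 0.65, 0.5, 0.3, 0.05), n_pred = rep(150L, 6))
  expect_equal(ccm_verdict(falling)$verdict, "non_causal")
  # Fisher's n switch: tiny libraries kill the test when n = L is used
  small <- make_curve(c(0.05, 0.2, 0.5, 0.7, 0.75), L = c(3, 6, 8, 9, 10),
                      n_pred = rep(100L, 5))
  expect_error(ccm_verdict(small, effective_n = "L"), "more than 3")
  expect_equal(ccm_verdict(small, effective_n = "n_pred")$verdict, "causal")
})

test_that("pearson significance matches an independent statistics routine", {
  x <- c(0.00123, 0.298746, -0.274138, -0.890592, -0.454671, -0.991647,
         0.060144, 1.340215, -0.492207, -0.620475)
  y <- c(0.490457, 0.50626, -0.031655, -1.375764, -0.256587, 0.19948,
         -1.314143, 0.212492, -2.147326, -1.599775)
  res <- pearson_significance(x, y)
  expect_equal(res$r, 0.41476775682634875, tolerance = 1e-10)
  expect_equal(res$p, 0.23333004449946113, tolerance = 1e-10)
  expect_equal(pearson_significance(x, x)$r, 1)
  expect_equal(pearson_significance(x, -x)$r, -1)
  expect_error(pearson_significance(x, rep(1, 10)), "constant")
})
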