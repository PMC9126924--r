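#' Improvement in cross-map skill across the library range
#'
#' Skill at the largest library size minus skill at the smallest — the
#' raw convergence index of a cross-map curve.
#'
#' @param curve A [ccm_curve()].
#' @return Scalar difference.
#' @export
delta_rho <- function(curve) {
  stopifnot(inherits(curve, "ccm_curve"))
  if (length(curve$library_sizes) < 2) {
    stopf("curve needs at least 2 library sizes")
  }
  curve$skill[length(curve$skill)] - curve$skill[1]
}

#' Fisher's z test for an increase in cross-map skill
#'
#' Tests whether the correlation at the largest library exceeds the one at
#' the smallest: both skills are z-transformed (\eqn{z = \mathrm{atanh}\
#' \rho}), the difference is standardized by
#' \eqn{\sqrt{1/(n_{max}-3) + 1/(n_{min}-3)}}, and the one-sided
#' upper-tail normal p-value is returned. Correlations at `|rho| >= 1` are
#' clamped to `1 - 1e-10` in magnitude (the result then carries a
#' `clamped` attribute).
#'
#' @param rho_max,rho_min Cross-map skill at the largest / smallest
#'   library size.
#' @param n_max,n_min Number of predicted points underlying each skill
#'   estimate (must be >= 4).
#' @return One-sided p-value, with attribute `z` (the test statistic).
#' @export
fisher_delta_rho_test <- function(rho_max, rho_min, n_max, n_min) {
  if (n_max <= 3 || n_min <= 3) {
    stopf("Fisher's z test needs more than 3 points per correlation")
  }
  clamped <- FALSE
  clamp <- function(r) {
    if (abs(r) >= 1) {
      clamped <<- TRUE
      return(sign(r) * (1 - 1e-10))
    }
    r
  }
  z_max <- atanh(clamp(rho_max))
  z_min <- atanh(clamp(rho_min))
  z <- (z_max - z_min) / sqrt(1 / (n_max - 3) + 1 / (n_min - 3))
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(p, z = z, clamped = clamped)
}

# Null distribution of the number of inversions (discordant pairs) of a
# random permutation of n distinct items: counts[d + 1] = number of
# permutations with d inversions. Cached per n.
inversion_count_cache <- new.env(parent = emptyenv())
inversion_counts <- function(n) {
  key <- as.character(n)
  if (!is.null(inversion_count_cache[[key]])) {
    return(inversion_count_cache[[key]])
  }
  counts <- 1
  if (n >= 2) {
    for (i in 2:n) {
      new <- numeric(length(counts) + i - 1)
      for (j in 0:(i - 1)) {
        idx <- seq_along(counts) + j
        new[idx] <- new[idx] + counts
      }
      counts <- new
    }
  }
  inversion_count_cache[[key]] <- counts
  counts
}

# Concordant/discordant pair counts and tie structure.
kendall_pair_counts <- function(x, y) {
  n <- length(x)
  C <- 0L; D <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) C <- C + 1L else if (s < 0) D <- D + 1L
    }
  }
  list(C = C, D = D)
}

#' Kendall trend test on a cross-map skill curve
#'
#' Kendall's tau between library sizes and skills, with a one-sided
#' p-value for an increasing trend. For up to 10 untied points the exact
#' permutation null distribution is used (via the inversion-number
#' distribution); with ties, tau-b and the tie-corrected normal
#' approximation. If all skills are tied the result is degenerate:
#' tau = 0, p = 1.
#'
#' @param curve A [ccm_curve()] with at least 3 library sizes, or a list
#'   with fields `library_sizes` and `skill`.
#' @return List with `tau`, `p`, `method`
#'   (`"exact"`, `"normal"`, or `"degenerate"`).
#' @export
kendall_trend_test <- function(curve) {
  x <- curve$library_sizes
  y <- curve$skill
  n <- length(x)
  if (n < 3) stopf("Kendall trend test needs at least 3 library sizes")
  if (length(unique(y)) == 1) {
    return(list(tau = 0, p = 1, method = "degenerate"))
  }
  pc <- kendall_pair_counts(x, y)
  S <- pc$C - pc$D
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  no_ties <- n1 == 0 && n2 == 0
  if (no_ties && n <= 10) {
    counts <- inversion_counts(n)
    # one-sided: P(S >= S_obs) = P(#discordant <= D_obs)
    p <- sum(counts[seq_len(pc$D + 1)]) / factorial(n)
    method <- "exact"
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_S <- (v0 - vt - vu) / 18 + v1 + v2
    p <- stats::pnorm(S / sqrt(var_S), lower.tail = FALSE)
    method <- "normal"
  }
  list(tau = tau, p = p, method = method)
}

#' Convergence verdict for a cross-map curve
#'
#' Computes the three convergence indices — the raw skill improvement
#' [delta_rho()], the one-sided [fisher_delta_rho_test()] p-value, and the
#' one-sided [kendall_trend_test()] p-value — and declares the direction
#' causal only when all three agree: both p-values below `alpha` and a
#' positive skill improvement. Convergence of cross-map skill with library
#' size, not raw skill or skill difference, is the defining criterion of
#' CCM causation.
#'
#' @param curve A [ccm_curve()].
#' @param alpha Significance level (default 0.05).
#' @param effective_n What to use as the per-correlation sample size in
#'   the Fisher test: `"n_pred"` (number of cross-map predicted points;
#'   default) or `"L"` (the library size itself).
#' @return An object of class `convergence_result`: list with
#'   `direction`, `delta_rho`, `fisher_p`, `kendall_tau`, `kendall_p`,
#'   `alpha`, `verdict` (`"causal"` / `"non_causal"`).
#' @export
ccm_verdict <- function(curve, alpha = 0.05,
                        effective_n = c("n_pred", "L")) {
  stopifnot(inherits(curve, "ccm_curve"))
  effective_n <- match.arg(effective_n)
  dr <- delta_rho(curve)
  k <- length(curve$library_sizes)
  n_max <- if (effective_n == "n_pred") curve$n_pred[k] else curve$library_sizes[k]
  n_min <- if (effective_n == "n_pred") curve$n_pred[1] else curve$library_sizes[1]
  fp <- fisher_delta_rho_test(curve$skill[k], curve$skill[1], n_max, n_min)
  kt <- kendall_trend_test(curve)
  verdict <- if (fp < alpha && kt$p < alpha && dr > 0) "causal" else "non_causal"
  structure(list(direction = curve$direction,
                 delta_rho = dr,
                 fisher_p = as.numeric(fp),
                 kendall_tau = kt$tau,
                 kendall_p = kt$p,
                 alpha = alpha,
                 verdict = verdict),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf("<convergence_result> %s: %s (delta_rho = %.3f, Fisher p = %.3g, Kendall tau = %.2f p = %.3g)\n",
              x$direction, x$verdict, x$delta_rho, x$fisher_p,
              x$kendall_tau, x$kendall_p))
  invisible(x)
}

#' Pearson correlation with significance
#'
#' Plain correlation test between two series: Pearson r and the two-sided
#' p-value from the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y Numeric series of equal length >= 4.
#' @return List with `r` and `p`.
#' @export
pearson_significance <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 4) stopf("need at least 4 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation is undefined for a constant series")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
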