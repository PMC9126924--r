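#' Parameters for (ensemble) empirical mode decomposition
#'
#' @param noise_level Ensemble noise level `r`: standard deviation of the
#'   added white noise as a fraction of the signal's standard deviation.
#'   The study default is 0.085. `noise_level = 0` requires
#'   `n_ensemble = 1` (plain sifting).
#' @param n_ensemble Ensemble size; the study default is 1000.
#' @param max_imfs Cap on the number of IMFs (`Inf` = until the remainder
#'   is monotone).
#' @param sift_threshold Cauchy-type stopping tolerance for the sifting
#'   loop: iteration stops when the normalized squared difference between
#'   successive sift iterates falls below this value (default 0.2, the
#'   original EMD convention).
#' @param max_sift_iters Hard cap on sifting iterations per IMF.
#' @param seed Integer RNG seed for the ensemble noise.
#' @return An object of class `eemd_params`.
#' @export
eemd_params <- function(noise_level = 0.085, n_ensemble = 1000,
                        max_imfs = Inf, sift_threshold = 0.2,
                        max_sift_iters = 50, seed = 1) {
  p <- list(noise_level = noise_level, n_ensemble = as.integer(n_ensemble),
            max_imfs = max_imfs, sift_threshold = sift_threshold,
            max_sift_iters = as.integer(max_sift_iters),
            seed = as.integer(seed))
  if (p$noise_level < 0) stopf("noise_level must be >= 0")
  if (p$n_ensemble < 1) stopf("n_ensemble must be >= 1")
  if (p$noise_level == 0 && p$n_ensemble != 1) {
    stopf("noise_level = 0 requires n_ensemble = 1")
  }
  if (p$sift_threshold <= 0) stopf("sift_threshold must be positive")
  if (p$max_sift_iters < 1) stopf("max_sift_iters must be >= 1")
  if (!identical(p$max_imfs, Inf) && p$max_imfs < 1) {
    stopf("max_imfs must be >= 1 (or Inf)")
  }
  structure(p, class = "eemd_params")
}

#' Construct an IMF decomposition object
#'
#' Mostly used internally by [sift()] and [eemd()], but exported so
#' synthetic decompositions (e.g. known orthogonal modes) can be built
#' directly.
#'
#' @param imfs Numeric matrix with one column per intrinsic mode function,
#'   ordered from highest to lowest frequency.
#' @param residual Residual trend series (same length as the IMFs).
#' @param params The [eemd_params()] used (optional).
#' @return An object of class `imf_decomposition` with fields `imfs`,
#'   `residual`, `source_length`, `params`.
#' @export
imf_decomposition <- function(imfs, residual, params = NULL) {
  imfs <- as.matrix(imfs)
  if (ncol(imfs) < 1) stopf("need at least one IMF")
  if (length(residual) != nrow(imfs)) {
    stopf("residual length must match IMF length")
  }
  colnames(imfs) <- paste0("imf", seq_len(ncol(imfs)))
  structure(list(imfs = imfs, residual = as.numeric(residual),
                 source_length = nrow(imfs), params = params),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMFs over %d samples\n",
              ncol(x$imfs), x$source_length))
  invisible(x)
}

#' Number of IMFs in a decomposition
#' @param decomp An `imf_decomposition`.
#' @return Integer IMF count.
#' @export
n_imfs <- function(decomp) ncol(decomp$imfs)

#' Reconstruct the source signal from a decomposition
#' @param decomp An `imf_decomposition`.
#' @return Numeric vector: row sums of the IMFs plus the residual.
#' @export
reconstruct <- function(decomp) rowSums(decomp$imfs) + decomp$residual

# Cubic-spline envelope through extrema, with mirror extension of (up to)
# two extrema beyond each end of the record. Natural splines keep the
# extrapolated ends tame.
spline_envelope <- function(idx, val, n) {
  k <- min(2L, length(idx))
  left_t <- 2 - idx[seq_len(k)]
  left_v <- val[seq_len(k)]
  ri <- rev(seq(length(idx) - k + 1L, length(idx)))
  right_t <- 2L * n - idx[ri]
  right_v <- val[ri]
  t <- c(left_t, idx, right_t)
  v <- c(left_v, val, right_v)
  o <- order(t)
  t <- t[o]; v <- v[o]
  keep <- !duplicated(t)
  stats::splinefun(t[keep], v[keep], method = "natural")(seq_len(n))
}

# Extract one IMF from x by iterated envelope-mean subtraction, or NULL if
# x has too few extrema to fit envelopes. Iteration stops once the
# Cauchy-type criterion is met AND the candidate satisfies the IMF
# property (extrema and zero-crossing counts differ by at most one,
# boundaries excluded), or at max_iter.
sift_one_imf <- function(x, threshold, max_iter) {
  h <- x
  n <- length(x)
  for (it in seq_len(max_iter)) {
    e <- find_extrema(h)
    if (length(e$maxima) < 2 || length(e$minima) < 2) {
      return(if (it == 1) NULL else h)
    }
    m <- (spline_envelope(e$maxima, h[e$maxima], n) +
          spline_envelope(e$minima, h[e$minima], n)) / 2
    h_new <- h - m
    sd_crit <- sum((h - h_new)^2) / sum(h^2)
    h <- h_new
    if (sd_crit < threshold && imf_property_holds(h)) break
  }
  h
}

# |#extrema - #zero-crossings| <= 1, ignoring 2 samples at each boundary.
imf_property_holds <- function(h) {
  if (length(h) < 8) return(TRUE)
  core <- h[3:(length(h) - 2)]
  n_ext <- sum(diff(sign(diff(core))) != 0)
  n_zc <- sum(abs(diff(sign(core))) == 2)
  abs(n_ext - n_zc) <= 1
}

#' Empirical mode decomposition by sifting
#'
#' Iteratively extracts intrinsic mode functions: the mean of the cubic
#' spline envelopes through local maxima and minima is subtracted from the
#' working signal until a Cauchy-type stopping rule fires, the resulting
#' IMF is removed, and the procedure repeats on the remainder until the
#' remainder is monotone (fewer than three extrema) or `max_imfs` is
#' reached. Because each IMF is removed by exact subtraction, the
#' completeness identity `signal = rowSums(imfs) + residual` holds to
#' machine precision.
#'
#' @param signal Numeric series of length >= 8 with at least some
#'   oscillation (a constant series is rejected).
#' @param params An [eemd_params()]; only the sifting fields are used and
#'   the noise level is treated as 0.
#' @return An [imf_decomposition()].
#' @export
sift <- function(signal, params = eemd_params(noise_level = 0, n_ensemble = 1)) {
  stopifnot(inherits(params, "eemd_params"))
  if (length(signal) < 8) stopf("signal too short for sifting (need >= 8 samples)")
  if (any(!is.finite(signal))) stopf("signal contains non-finite values")
  if (stats::sd(signal) == 0) stopf("signal is constant; nothing to decompose")
  imfs <- list()
  rem <- signal
  while (length(imfs) < params$max_imfs) {
    e <- find_extrema(rem)
    if (length(e$maxima) + length(e$minima) < 3) break
    imf <- sift_one_imf(rem, params$sift_threshold, params$max_sift_iters)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1L]] <- imf
    rem <- rem - imf
  }
  if (!length(imfs)) stopf("no IMF could be extracted (too few extrema)")
  imf_decomposition(do.call(cbind, imfs), rem, params)
}

#' Ensemble empirical mode decomposition
#'
#' For each ensemble member, white noise with standard deviation
#' `noise_level * sd(signal)` is added to the signal and [sift()] applied;
#' the k-th IMFs are then averaged across members, truncating to the
#' minimum IMF count observed. The residual is defined as the signal minus
#' the summed averaged IMFs, so reconstruction remains exact. With
#' `noise_level = 0` and `n_ensemble = 1` the result is identical to
#' [sift()].
#'
#' @param signal Numeric series (length >= 8).
#' @param params An [eemd_params()].
#' @return An [imf_decomposition()].
#' @export
eemd <- function(signal, params = eemd_params()) {
  stopifnot(inherits(params, "eemd_params"))
  if (params$noise_level == 0 && params$n_ensemble == 1) {
    return(sift(signal, params))
  }
  if (length(signal) < 8) stopf("signal too short for sifting (need >= 8 samples)")
  if (any(!is.finite(signal))) stopf("signal contains non-finite values")
  if (stats::sd(signal) == 0) stopf("signal is constant; nothing to decompose")
  noise_sd <- params$noise_level * stats::sd(signal)
  decs <- with_seed(params$seed, lapply(seq_len(params$n_ensemble), function(i) {
    sift(signal + stats::rnorm(length(signal), sd = noise_sd), params)
  }))
  k <- min(vapply(decs, n_imfs, integer(1)))
  if (!identical(params$max_imfs, Inf)) k <- min(k, params$max_imfs)
  imfs <- vapply(seq_len(k), function(j) {
    rowMeans(vapply(decs, function(d) d$imfs[, j], numeric(length(signal))))
  }, numeric(length(signal)))
  imf_decomposition(imfs, signal - rowSums(as.matrix(imfs)), params)
}

#' Index of orthogonality of an IMF decomposition
#'
#' The standard overall index
#' \deqn{IO = \sum_{j < k} |\langle c_j, c_k \rangle| / \langle s, s \rangle}
#' where \eqn{c_j} are the IMFs and \eqn{s} is the reconstructed signal
#' (IMFs plus residual). Exactly orthogonal modes give 0; a single-IMF
#' decomposition is defined as 0. The index is invariant to global scaling
#' of the signal.
#'
#' @param decomp An [imf_decomposition()].
#' @return Non-negative scalar.
#' @export
orthogonality_index <- function(decomp) {
  stopifnot(inherits(decomp, "imf_decomposition"))
  k <- n_imfs(decomp)
  if (k < 2) return(0)
  s <- reconstruct(decomp)
  cross <- crossprod(decomp$imfs)
  sum(abs(cross[upper.tri(cross)])) / sum(s * s)
}

#' Spectral separability of two IMF decompositions
#'
#' Quantifies how distinctly adjacent IMF scales occupy separate frequency
#' bands: for every adjacent IMF pair (within each decomposition) the
#' overlap of their unit-normalized periodograms is computed, and the index
#' is the mean of `1 - overlap` pooled across both decompositions. Disjoint
#' bands give 1; an empty adjacent-pair set (both decompositions single-IMF)
#' is defined as 1.
#'
#' @param decomp_x,decomp_y [imf_decomposition()] objects.
#' @return Scalar in `[0, 1]`.
#' @export
separability_index <- function(decomp_x, decomp_y) {
  stopifnot(inherits(decomp_x, "imf_decomposition"),
            inherits(decomp_y, "imf_decomposition"))
  pair_sep <- function(decomp) {
    k <- n_imfs(decomp)
    if (k < 2) return(numeric(0))
    specs <- apply(decomp$imfs, 2, function(c) {
      p <- periodogram(c)$power
      p / sum(p)
    })
    vapply(seq_len(k - 1), function(j) {
      1 - sum(pmin(specs[, j], specs[, j + 1]))
    }, numeric(1))
  }
  seps <- c(pair_sep(decomp_x), pair_sep(decomp_y))
  if (!length(seps)) return(1)
  mean(seps)
}

#' Select the EEMD noise level by the separability/orthogonality criterion
#'
#' Decomposes both series at each candidate noise level, discards
#' candidates whose orthogonality index (the worse of the two series)
#' exceeds `orthogonality_threshold`, and among the survivors returns the
#' level maximizing [separability_index()]. If no candidate passes the
#' orthogonality screen, the one with the smallest orthogonality index is
#' returned and the result is flagged.
#'
#' @param x,y Numeric series.
#' @param candidate_levels Non-empty vector of candidate noise levels
#'   (each >= 0).
#' @param params An [eemd_params()]; its `noise_level` is overridden by
#'   each candidate (a zero candidate is decomposed with a single-member
#'   ensemble). The same seed is used for every candidate so the choice is
#'   deterministic and order-invariant.
#' @param orthogonality_threshold Acceptance bound on the orthogonality
#'   index (default 0.1).
#' @return The chosen noise level, with attributes `flagged` (logical) and
#'   `table` (per-candidate diagnostics).
#' @export
select_noise_level <- function(x, y, candidate_levels,
                               params = eemd_params(),
                               orthogonality_threshold = 0.1) {
  if (!length(candidate_levels)) stopf("candidate_levels must be non-empty")
  if (any(candidate_levels < 0)) stopf("candidate levels must be >= 0")
  levels <- candidate_levels
  tab <- do.call(rbind, lapply(levels, function(r) {
    p <- eemd_params(noise_level = r,
                     n_ensemble = if (r == 0) 1L else params$n_ensemble,
                     max_imfs = params$max_imfs,
                     sift_threshold = params$sift_threshold,
                     max_sift_iters = params$max_sift_iters,
                     seed = params$seed)
    dx <- eemd(x, p); dy <- eemd(y, p)
    data.frame(noise_level = r,
               orthogonality_x = orthogonality_index(dx),
               orthogonality_y = orthogonality_index(dy),
               separability = separability_index(dx, dy))
  }))
  tab$orthogonality <- pmax(tab$orthogonality_x, tab$orthogonality_y)
  ok <- tab$orthogonality <= orthogonality_threshold
  if (any(ok)) {
    cand <- tab[ok, ]
    # deterministic under reordered candidate lists: break separability
    # ties toward the smaller noise level
    cand <- cand[order(-cand$separability, cand$noise_level), ]
    chosen <- cand$noise_level[1]
    flagged <- FALSE
  } else {
    cand <- tab[order(tab$orthogonality, tab$noise_level), ]
    chosen <- cand$noise_level[1]
    flagged <- TRUE
  }
  structure(chosen, flagged = flagged, table = tab)
}
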