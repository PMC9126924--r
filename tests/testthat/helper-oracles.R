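# Independent reference implementations used as oracles. These share no
# code with the package internals they check.

# Plain-R simplex cross map with an explicit library index set (no
# subsampling): x's delay vectors estimate y at the same time, using up to
# E + 1 nearest neighbors and exponential weights.
naive_xmap_rho <- function(x, y, E, tau, lib) {
  offset <- (E - 1) * tau
  n <- length(x) - offset
  M <- sapply(0:(E - 1), function(j) x[(1 + offset - j * tau):(length(x) - j * tau)])
  if (is.null(dim(M))) M <- matrix(M, ncol = 1)
  yt <- y[(1:n) + offset]
  pred <- rep(NA_real_, n)
  for (i in 1:n) {
    cand <- setdiff(lib, i)
    if (!length(cand)) next
    d <- sqrt(colSums((t(M[cand, , drop = FALSE]) - M[i, ])^2))
    o <- order(d, cand)
    k <- min(E + 1, length(cand))
    nb <- o[1:k]
    dn <- d[nb]
    w <- if (dn[1] == 0) as.numeric(dn == 0) else exp(-dn / dn[1])
    pred[i] <- sum(w * yt[cand[nb]]) / sum(w)
  }
  ok <- !is.na(pred)
  if (sd(pred[ok]) == 0 || sd(yt[ok]) == 0) return(0)
  cor(pred[ok], yt[ok])
}

# Brute-force Kendall trend: concordant/discordant counts and the exact
# one-sided p by enumerating every permutation of y (n <= 8).
brute_kendall <- function(x, y) {
  n <- length(x)
  stat <- function(yy) {
    s <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(yy[j] - yy[i])
    }
    s
  }
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  S_obs <- stat(y)
  null_S <- vapply(perms(seq_len(n)), function(p) stat(y[p]), numeric(1))
  list(S = S_obs, tau = S_obs / choose(n, 2),
       p = mean(null_S >= S_obs))
}

# First-return logistic map series for deterministic-prediction checks.
logistic_series <- function(n, r = 3.9, x0 = 0.31) {
  x <- numeric(n)
  x[1] <- x0
  for (t in 1:(n - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  x
}

# Small local helpers independent of package internals.
find_local_maxima_for_test <- function(x) which(diff(sign(diff(x))) < 0) + 1

dominant_peak_for_test <- function(x) {
  sp <- stats::spec.pgram(x - mean(x), taper = 0, detrend = FALSE,
                          plot = FALSE, fast = FALSE)
  i <- which.max(sp$spec)
  list(freq = sp$freq[i], power = sp$spec[i])
}
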