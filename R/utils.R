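# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

# Indices of local maxima / minima of a series. Plateaus are handled by
# carrying the last non-zero slope sign forward, so a flat-topped peak
# counts once (at its left shoulder).
find_extrema <- function(x) {
  dx <- diff(x)
  s <- sign(dx)
  z <- s == 0
  if (any(z)) {
    for (i in which(z)) s[i] <- if (i > 1) s[i - 1] else 1
  }
  ds <- diff(s)
  list(maxima = which(ds < 0) + 1L, minima = which(ds > 0) + 1L)
}

# Smoothed-free periodogram of a series; returns freq (cycles/sample)
# and power, excluding the zero frequency.
periodogram <- function(x) {
  sp <- stats::spec.pgram(x - mean(x), taper = 0, detrend = FALSE,
                          plot = FALSE, fast = FALSE)
  list(freq = sp$freq, power = sp$spec)
}

# Frequency and power of the dominant (non-zero) spectral peak.
dominant_peak <- function(x) {
  pg <- periodogram(x)
  i <- which.max(pg$power)
  list(freq = pg$freq[i], power = pg$power[i])
}

# Count of interior local maxima (used by oscillation-persistence checks).
count_local_maxima <- function(x) length(find_extrema(x)$maxima)

# Replace non-representable values so a report list survives JSON
# serialization untouched elsewhere.
sanitize_for_json <- function(x) {
  if (is.list(x)) return(lapply(x, sanitize_for_json))
  if (is.numeric(x)) {
    x[is.infinite(x)] <- NA
    return(x)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
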