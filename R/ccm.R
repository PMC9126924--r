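#' Parameters for convergent cross mapping
#'
#' @param E Embedding dimension (integer >= 1).
#' @param tau Embedding lag (integer >= 1).
#' @param tp Prediction lag (0 = nowcast, the CCM convention).
#' @param library_sizes Strictly increasing vector of library sizes, each
#'   >= 2. A library size is the number of delay vectors available as
#'   nearest-neighbor donors; requested sizes beyond the number of
#'   available vectors fall back to the full (deterministic) set.
#' @param n_subsamples Random library draws per size (each drawn without
#'   replacement); at or beyond the full set a single deterministic draw
#'   is used.
#' @param exclusion_radius Theiler window: library points within this many
#'   time steps of the target are excluded (0 = exclude the target only).
#' @param seed Integer RNG seed for the library draws. The subsample
#'   stream restarts from this seed at every library size, so individual
#'   sizes can be recomputed independently and reproducibly.
#' @return An object of class `ccm_params`.
#' @export
ccm_params <- function(E = 2, tau = 1, tp = 0,
                       library_sizes = 2:10, n_subsamples = 100,
                       exclusion_radius = 0, seed = 1) {
  p <- list(E = as.integer(E), tau = as.integer(tau), tp = as.integer(tp),
            library_sizes = as.integer(library_sizes),
            n_subsamples = as.integer(n_subsamples),
            exclusion_radius = as.integer(exclusion_radius),
            seed = as.integer(seed))
  if (p$E < 1) stopf("E must be >= 1")
  if (p$tau < 1) stopf("tau must be >= 1")
  if (!length(p$library_sizes)) stopf("library_sizes must be non-empty")
  if (any(diff(p$library_sizes) <= 0)) {
    stopf("library_sizes must be strictly increasing")
  }
  if (min(p$library_sizes) < 2) stopf("library sizes must be >= 2")
  if (p$n_subsamples < 1) stopf("n_subsamples must be >= 1")
  if (p$exclusion_radius < 0) stopf("exclusion_radius must be >= 0")
  structure(p, class = "ccm_params")
}

#' Delay-coordinate embedding
#'
#' Builds the delay vectors
#' \eqn{v(t) = [s(t), s(t - \tau), \ldots, s(t - (E-1)\tau)]} for all
#' admissible t. With `E = 1` the vectors are the scalar series itself.
#'
#' @param series Numeric series of length >= `(E - 1) * tau + 1`.
#' @param E Embedding dimension.
#' @param tau Embedding lag.
#' @return Numeric matrix with `length(series) - (E - 1) * tau` rows and
#'   `E` columns; row i corresponds to series time `i + (E - 1) * tau`.
#' @export
delay_embed <- function(series, E, tau = 1) {
  E <- as.integer(E); tau <- as.integer(tau)
  n <- length(series)
  need <- (E - 1L) * tau + 1L
  if (n < need) {
    stopf("series of length %d is too short for E = %d, tau = %d (need >= %d)",
          n, E, tau, need)
  }
  offset <- (E - 1L) * tau
  vapply(0:(E - 1L), function(j) {
    series[(1L + offset - j * tau):(n - j * tau)]
  }, numeric(n - offset))
}

# Shared plumbing: embedding of x, aligned targets of y (NA where the
# prediction time falls outside the record), pairwise distances.
xmap_setup <- function(x, y, params) {
  emb <- delay_embed(x, params$E, params$tau)
  if (is.null(dim(emb))) emb <- matrix(emb, ncol = params$E)
  n <- nrow(emb)
  offset <- (params$E - 1L) * params$tau
  target_times <- seq_len(n) + offset + params$tp
  y_target <- rep(NA_real_, n)
  ok <- target_times >= 1L & target_times <= length(y)
  y_target[ok] <- y[target_times[ok]]
  if (!any(ok)) stopf("no usable prediction targets (check tp)")
  list(dist = as.matrix(stats::dist(emb)), y_target = y_target, n = n,
       times = seq_len(n))
}

# One library size given a prepared setup; draws happen in the caller's
# RNG stream.
xmap_one_size <- function(setup, L, params) {
  n <- setup$n
  L_eff <- min(L, n)
  libs <- if (L_eff >= n) {
    matrix(seq_len(n), nrow = 1)
  } else {
    t(vapply(seq_len(params$n_subsamples),
             function(i) sample.int(n, L_eff), integer(L_eff)))
  }
  res <- simplex_xmap_cpp(setup$dist, setup$y_target, libs,
                          params$E + 1L, params$exclusion_radius,
                          as.integer(setup$times))
  if (all(res$n_pred == 0)) stopf("no usable targets at library size %d", L)
  list(rho_mean = mean(res$rho),
       rho_sd = if (length(res$rho) > 1) stats::sd(res$rho) else 0,
       n_pred = as.integer(round(mean(res$n_pred))),
       degenerate = any(res$degenerate))
}

#' Cross-map skill at one library size
#'
#' Simplex-projection cross mapping: the delay-coordinate manifold of `x`
#' is used to estimate `y`. For each random draw of `L` library vectors,
#' each target point is estimated from its (up to) `E + 1` nearest library
#' neighbors with exponential distance weights
#' \eqn{w_i = \exp(-d_i / d_{min})}, and skill is the Pearson correlation
#' between estimates and observations over all targets. High skill of
#' "x cross-maps y" is evidence that y causally forces x (the effect
#' variable encodes its driver).
#'
#' When fewer than `E + 1` usable neighbors exist (tiny libraries), the
#' available ones are used; a constant estimate or constant truth gives
#' skill 0 with a degeneracy flag.
#'
#' @param x Series whose manifold donates neighbors.
#' @param y Series being estimated.
#' @param L Library size (number of delay vectors; capped at the number
#'   available).
#' @param params A [ccm_params()]; `library_sizes` is ignored here. Draws
#'   are made under `params$seed`.
#' @return List with `rho_mean`, `rho_sd`, `n_pred`, `degenerate`.
#' @export
cross_map_skill <- function(x, y, L, params = ccm_params()) {
  stopifnot(inherits(params, "ccm_params"))
  if (L < 2) stopf("L must be >= 2")
  setup <- xmap_setup(x, y, params)
  with_seed(params$seed, xmap_one_size(setup, L, params))
}

#' Cross-map skill as a function of library size
#'
#' Runs [cross_map_skill()] over `params$library_sizes`, restarting the
#' subsample stream from `params$seed` at each size, and returns the skill
#' curve used by the convergence tests.
#'
#' @param x Series whose manifold donates neighbors.
#' @param y Series being estimated.
#' @param params A [ccm_params()].
#' @param direction Label for the curve (default `"X_xmap_Y"`, meaning the
#'   manifold of X estimates Y — evidence that Y forces X).
#' @return An object of class `ccm_curve`: a list with `direction`,
#'   `library_sizes`, `skill`, `skill_sd`, `n_pred`, `params`.
#' @export
ccm_curve <- function(x, y, params = ccm_params(),
                      direction = "X_xmap_Y") {
  stopifnot(inherits(params, "ccm_params"))
  setup <- xmap_setup(x, y, params)
  res <- lapply(params$library_sizes, function(L) {
    with_seed(params$seed, xmap_one_size(setup, L, params))
  })
  structure(list(direction = direction,
                 library_sizes = params$library_sizes,
                 skill = vapply(res, `[[`, numeric(1), "rho_mean"),
                 skill_sd = vapply(res, `[[`, numeric(1), "rho_sd"),
                 n_pred = vapply(res, `[[`, integer(1), "n_pred"),
                 degenerate = vapply(res, `[[`, logical(1), "degenerate"),
                 params = params),
            class = "ccm_curve")
}

#' @export
print.ccm_curve <- function(x, ...) {
  cat(sprintf("<ccm_curve> %s\n", x$direction))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.ccm_curve <- function(x, ...) {
  data.frame(direction = x$direction, L = x$library_sizes,
             rho_mean = x$skill, rho_sd = x$skill_sd, n_pred = x$n_pred)
}

#' Select the embedding dimension by univariate simplex self-prediction
#'
#' For each candidate E, the series is embedded and its own future
#' (`tp` steps ahead) predicted by leave-one-out simplex projection with
#' the full library; the E maximizing prediction skill is returned, with
#' ties broken toward smaller E. Deterministic: no random draws are
#' involved.
#'
#' @param series Numeric series.
#' @param E_grid Candidate embedding dimensions (non-empty).
#' @param tau Embedding lag.
#' @param tp Prediction horizon for the self-prediction criterion
#'   (default 1).
#' @param tol Parsimony tolerance: the smallest E whose skill comes
#'   within `tol` of the maximum is selected (default 0.01), so near-ties
#'   resolve toward lower dimensions.
#' @return The selected E, with attribute `skill` (per-candidate rho).
#' @export
select_embedding <- function(series, E_grid = 1:8, tau = 1, tp = 1,
                             tol = 0.01) {
  if (!length(E_grid)) stopf("E_grid must be non-empty")
  o <- order(E_grid)
  E_grid <- E_grid[o]
  skills <- vapply(E_grid, function(E) {
    params <- ccm_params(E = E, tau = tau, tp = tp,
                         library_sizes = c(2L, 3L), n_subsamples = 1)
    setup <- xmap_setup(series, series, params)
    xmap_one_size(setup, setup$n, params)$rho_mean
  }, numeric(1))
  best <- E_grid[which(skills >= max(skills) - tol)[1]]
  structure(best, skill = stats::setNames(skills, paste0("E", E_grid)))
}
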