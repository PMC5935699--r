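# Independent brute-force oracles used across the test files.
#
# The path-enumeration oracle computes the model evidence and the
# smoothed per-step posteriors of the discretized two-level model by
# explicit summation over every parameter path (i_1, ..., i_T): the
# probability of a path is prior mass x transition-kernel entries x
# likelihood factors. It shares no code with the iterative engine
# except the materialized one-step kernel matrix (columns of the
# transformation applied to unit masses).

# per-step likelihood matrix (steps x cells); NA data points contribute
# a flat improper factor of one
oracle_lik_matrix <- function(data, obs, d_prev0 = 0) {
  t(vapply(seq_along(data), function(t) {
    if (is.na(data[t])) return(rep(1, obs$grid$size))
    d_prev <- if (!obs$depends_on_prev) NULL
      else if (t == 1L || is.na(data[t - 1L])) d_prev0 else data[t - 1L]
    likelihood(obs, data[t], t = t, d_prev = d_prev)
  }, numeric(obs$grid$size)))
}

# evidence and smoothed posteriors by explicit path enumeration
oracle_paths <- function(data, obs, trans, prior, d_prev0 = 0) {
  grid <- obs$grid
  n <- grid$size
  T_ <- length(data)
  stopifnot(n^T_ <= 2e5)
  L <- oracle_lik_matrix(data, obs, d_prev0)
  prior_mass <- prior$w * grid$voxel
  kernels <- lapply(seq_len(max(T_ - 1L, 1L)), function(t) {
    transition_matrix(trans, grid, direction = "forward", t = t)
  })
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), T_)))
  pp <- prior_mass[paths[, 1]] * L[cbind(1L, paths[, 1])]
  if (T_ > 1L) {
    for (t in 2:T_) {
      pp <- pp * kernels[[t - 1L]][cbind(paths[, t], paths[, t - 1L])] *
        L[cbind(t, paths[, t])]
    }
  }
  evidence <- sum(pp)
  smoothed <- matrix(0, T_, n)
  for (t in seq_len(T_)) {
    for (i in seq_len(n)) {
      smoothed[t, i] <- sum(pp[paths[, t] == i])
    }
  }
  smoothed <- smoothed / evidence / grid$voxel # density per voxel
  list(evidence = evidence, smoothed = smoothed)
}

# random normalized lattice distribution (for property tests)
random_dist <- function(grid) {
  w <- stats::rgamma(grid$size, shape = 0.7)
  grid_normalize(grid_dist(grid, w))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(
    all(abs(actual - expected) <= tol * pmax(abs(expected), 1e-300)),
    label = sprintf(
      "max relative deviation %.3g (tolerance %.1g)",
      max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol
    )
  )
}
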