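# High-level (transition) models.
#
# A transition model is a norm-preserving linear transformation T of the
# lattice weights, applied between time steps; it encodes how the
# low-level parameters may change. Every transformation here is
# column-stochastic when written as a matrix acting on weight vectors:
# each source cell redistributes exactly its own mass, so the norm of
# any input distribution is preserved and the forward recursion is
# equivalent to summing over all parameter paths of a Markov kernel.
# The backward variant T' used by the smoothing recursion is the exact
# adjoint of the forward kernel, so that alpha * beta reproduces the
# conditional posterior of the underlying Markov chain to machine
# precision. In the lattice interior the adjoint coincides with the
# intuitive backward dynamics: Gaussian kernels and jump mixtures are
# self-adjoint, deterministic shifts negate their displacement; the two
# differ only in how the truncated boundary is treated.

new_transition <- function(kind, fields = list()) {
  structure(c(list(kind = kind), fields),
            class = c(paste0("trans_", kind), "transition"))
}

#' Identity transition (constant parameters)
#' @export
trans_identity <- function() new_transition("identity")

#' Gaussian random-walk transition
#'
#' Discrete convolution with a Gaussian kernel of standard deviation
#' `sigma` (per dimension), letting the parameters drift gradually. The
#' kernel weights are cell-boundary CDF differences, which stays accurate
#' when `sigma < ` grid spacing; mass that would diffuse past the lattice
#' boundary is retained by renormalizing each source cell's kernel column
#' to one, so the transformation is exactly norm-preserving on the
#' truncated support. `sigma = 0` components are the identity. The kernel
#' is symmetric, so forward and backward applications coincide.
#'
#' @param sigma numeric vector of kernel standard deviations, one per
#'   grid dimension (recycled if scalar), in parameter units per step.
#' @export
trans_gaussian_rw <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma < 0)) {
    stop_arg("sigma", "kernel standard deviations must be >= 0")
  }
  new_transition("gaussian_rw", list(sigma = sigma))
}

#' Minimal-probability transition (abrupt jumps)
#'
#' Adds a small constant to the posterior followed by a norm-preserving
#' rescaling: `T(w) = (1 - p_min) w + p_min * flat * norm(w)`. Every
#' cell thus always carries at least `p_min` times the density of a flat
#' distribution, which lets the parameters jump anywhere within one
#' step. `p_min = 0` is the identity, `p_min = 1` a full flat reset.
#'
#' @param p_min relative probability floor in `[0, 1]`.
#' @export
trans_minimal_prob <- function(p_min) {
  check_scalar(p_min, "p_min")
  if (p_min < 0 || p_min > 1) stop_arg("p_min", "must be in [0, 1]")
  new_transition("minimal_prob", list(p_min = p_min))
}

#' Reset transition (change-point)
#'
#' Replaces the distribution by `reset_prior` scaled to the input norm,
#' erasing all parameter memory. With `reset_prior = NULL` the flat
#' distribution is used ("flat reset").
#'
#' @param reset_prior a normalized [grid_dist], or `NULL` for flat.
#' @export
trans_reset <- function(reset_prior = NULL) {
  if (!is.null(reset_prior)) {
    stopifnot(inherits(reset_prior, "grid_dist"))
    reset_prior <- grid_normalize(reset_prior)
  }
  new_transition("reset", list(reset_prior = reset_prior))
}

#' Deterministic shift transition (trend)
#'
#' Shifts the distribution along one dimension by `delta` parameter
#' units with linear sub-cell interpolation; mass pushed past the
#' lattice edge accumulates in the edge cell, so the total mass is
#' conserved exactly. `delta` may be a constant or a function of the
#' step index `t`, returning the displacement applied in the transition
#' from `t` to `t + 1`; a deterministic trend `mu_t = f(t)` is realized
#' by `delta(t) = f(t + 1) - f(t)`. The backward variant negates the
#' displacement (non-reversible dynamics need the separate backward
#' transformation).
#'
#' @param delta numeric constant or `function(t)`.
#' @param dim name of the dimension to shift; defaults to the first.
#' @export
trans_shift <- function(delta, dim = NULL) {
  if (!is.function(delta)) check_scalar(delta, "delta")
  new_transition("shift", list(
    delta = delta, dim = dim,
    time_dependent = is.function(delta)
  ))
}

#' Composite transition
#'
#' Applies component transitions in order in the forward direction and
#' in reverse order, each with its backward variant, in the backward
#' direction.
#'
#' @param ... transition models.
#' @export
trans_compose <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "transition")) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "transition")))
  new_transition("composite", list(parts = parts))
}

#' Time-scheduled transition
#'
#' Delegates to `pick(t)`, which must return the transition model
#' governing the step from `t` to `t + 1`. Used for change-point models
#' where a reset replaces the regular dynamics at a single step.
#'
#' @param pick `function(t)` returning a transition model.
#' @export
trans_schedule <- function(pick) {
  stopifnot(is.function(pick))
  new_transition("schedule", list(pick = pick))
}

# Resolve the (possibly time-dependent) transition acting between step t
# and t + 1.
#' @keywords internal
#' @noRd
transition_at <- function(tm, t) {
  if (inherits(tm, "trans_schedule")) {
    return(transition_at(tm$pick(t), t))
  }
  tm
}

#' Apply a transition model to a lattice distribution
#'
#' @param tm a transition model.
#' @param dist a [grid_dist].
#' @param direction `"forward"` or `"backward"`.
#' @param t step index of the transition (from `t` to `t + 1`); only
#'   time-dependent models use it.
#' @return A [grid_dist] with the same norm as the input.
#' @export
apply_transition <- function(tm, dist, direction = c("forward", "backward"),
                             t = 1L) {
  direction <- match.arg(direction)
  stopifnot(inherits(dist, "grid_dist"))
  tm <- transition_at(tm, t)
  w <- apply_transition_w(tm, dist$w, dist$grid, direction, t)
  grid_dist(dist$grid, w)
}

# Weight-vector workhorse used by the engine (avoids re-wrapping).
#' @keywords internal
#' @noRd
apply_transition_w <- function(tm, w, grid, direction, t) {
  UseMethod("apply_transition_w")
}

#' @export
apply_transition_w.trans_identity <- function(tm, w, grid, direction, t) w

#' @export
apply_transition_w.trans_gaussian_rw <- function(tm, w, grid, direction, t) {
  sigma <- rep_len(tm$sigma, length(grid$n))
  adjoint <- direction == "backward"
  for (d in seq_along(grid$n)) {
    if (sigma[d] > 0 && grid$n[d] > 1L) {
      w <- conv_gauss_dim(w, grid, d, sigma[d], adjoint = adjoint)
    }
  }
  w
}

#' @export
apply_transition_w.trans_minimal_prob <- function(tm, w, grid, direction, t) {
  p <- tm$p_min
  if (p == 0) return(w)
  flat <- sum(w) / grid$size
  (1 - p) * w + p * flat
}

#' @export
apply_transition_w.trans_reset <- function(tm, w, grid, direction, t) {
  pw <- if (is.null(tm$reset_prior)) {
    rep(1 / (grid$size * grid$voxel), grid$size)
  } else {
    if (!identical(tm$reset_prior$grid$n, grid$n) ||
        !isTRUE(all.equal(tm$reset_prior$grid$centers, grid$centers,
                          check.attributes = FALSE))) {
      stop("reset prior is defined on a different grid")
    }
    tm$reset_prior$w
  }
  if (direction == "forward") {
    pw * (sum(w) * grid$voxel)
  } else {
    # adjoint: every source cell receives the prior-weighted average of
    # the incoming backward message
    rep(sum(pw * w) * grid$voxel, grid$size)
  }
}

#' @export
apply_transition_w.trans_shift <- function(tm, w, grid, direction, t) {
  delta <- if (is.function(tm$delta)) tm$delta(t) else tm$delta
  if (delta == 0) return(w)
  dim_name <- if (is.null(tm$dim)) grid$dim_names[1] else tm$dim
  d <- match(dim_name, grid$dim_names)
  if (is.na(d)) stop_arg("dim", paste("unknown dimension", dim_name))
  shift_dim(w, grid, d, delta, adjoint = direction == "backward")
}

#' @export
apply_transition_w.trans_composite <- function(tm, w, grid, direction, t) {
  parts <- if (direction == "forward") tm$parts else rev(tm$parts)
  for (p in parts) {
    w <- apply_transition_w(transition_at(p, t), w, grid, direction, t)
  }
  w
}

#' @export
apply_transition_w.trans_schedule <- function(tm, w, grid, direction, t) {
  apply_transition_w(transition_at(tm, t), w, grid, direction, t)
}

# ---- kernels ---------------------------------------------------------

# Gaussian kernel from cell-boundary CDF differences, half-width capped
# at the lattice extent. Returns the symmetric kernel vector of length
# 2h + 1.
#' @keywords internal
#' @noRd
gauss_kernel <- function(sigma, delta, n) {
  h <- min(n - 1L, as.integer(ceiling(8 * sigma / delta)))
  m <- (-h):h
  k <- stats::pnorm((m + 0.5) * delta, sd = sigma) -
    stats::pnorm((m - 0.5) * delta, sd = sigma)
  k / sum(k)
}

# Open (zero-padded) convolution of each column of `x` with kernel `k`,
# returning the central `nrow(x)` rows. Direct filtering for small
# problems, FFT for large ones.
#' @keywords internal
#' @noRd
conv_cols <- function(x, k) {
  n <- nrow(x)
  h <- (length(k) - 1L) %/% 2L
  pad <- matrix(0, h, ncol(x))
  xp <- rbind(pad, x, pad)
  if (n * length(k) <= 262144L) {
    out <- stats::filter(xp, k, method = "convolution", sides = 2L)
    out <- out[(h + 1L):(h + n), , drop = FALSE]
  } else {
    m <- nrow(xp) + length(k) - 1L
    nf <- stats::nextn(m, 2L)
    kf <- stats::fft(c(k, rep(0, nf - length(k))))
    xf <- stats::mvfft(rbind(xp, matrix(0, nf - nrow(xp), ncol(xp))))
    out <- Re(stats::mvfft(xf * kf, inverse = TRUE)) / nf
    out <- out[(2L * h + 1L):(2L * h + n), , drop = FALSE]
    out[out < 0] <- 0
  }
  out
}

# One-dimensional Gaussian smoothing along dimension `d` of the flattened
# weight array, with per-source-cell boundary renormalization so each
# kernel column sums to one (exactly norm-preserving, exactly linear).
# The adjoint (used by the backward recursion) convolves first and then
# divides by the boundary factors.
#' @keywords internal
#' @noRd
conv_gauss_dim <- function(w, grid, d, sigma, adjoint = FALSE) {
  n <- grid$n
  nd <- n[d]
  k <- gauss_kernel(sigma, grid$delta[d], nd)
  # in-lattice kernel mass per source cell
  cfac <- conv_cols(matrix(1, nd, 1L), k)[, 1L]
  smooth1 <- function(mat) {
    if (adjoint) conv_cols(mat, k) / cfac else conv_cols(mat / cfac, k)
  }
  if (length(n) == 1L) {
    return(smooth1(matrix(w, ncol = 1L))[, 1L])
  }
  # move dimension d to the front, smooth columns, move back
  perm <- c(d, seq_along(n)[-d])
  arr <- aperm(array(w, dim = n), perm)
  mat <- smooth1(matrix(arr, nrow = nd))
  arr <- array(mat, dim = n[perm])
  as.numeric(aperm(arr, order(perm)))
}

# Mass-conserving sub-cell shift along dimension `d` by `delta` units;
# overflow accumulates in the edge cells. The adjoint (backward message
# operator) pulls values back from the shifted location with edge
# replication, which in the interior equals a shift by -delta.
#' @keywords internal
#' @noRd
shift_dim <- function(w, grid, d, delta, adjoint = FALSE) {
  n <- grid$n
  nd <- n[d]
  steps <- delta / grid$delta[d]
  k0 <- floor(steps)
  f <- steps - k0
  push_int <- function(x, k) {
    if (k == 0) return(x)
    y <- numeric(nd)
    if (k > 0) {
      if (k >= nd) {
        y[nd] <- sum(x)
      } else {
        y[(k + 1):nd] <- x[1:(nd - k)]
        y[nd] <- y[nd] + sum(x[(nd - k + 1):nd])
      }
    } else {
      k <- -k
      if (k >= nd) {
        y[1] <- sum(x)
      } else {
        y[1:(nd - k)] <- x[(k + 1):nd]
        y[1] <- y[1] + sum(x[1:k])
      }
    }
    y
  }
  pull_int <- function(x, k) {
    # adjoint of push_int: value at source j is value at clamped j + k
    x[pmin(pmax(seq_len(nd) + k, 1L), nd)]
  }
  shift_vec <- function(x) {
    if (adjoint) {
      (1 - f) * pull_int(x, k0) + f * pull_int(x, k0 + 1L)
    } else {
      (1 - f) * push_int(x, k0) + f * push_int(x, k0 + 1L)
    }
  }
  if (length(n) == 1L) return(shift_vec(w))
  perm <- c(d, seq_along(n)[-d])
  arr <- aperm(array(w, dim = n), perm)
  mat <- matrix(arr, nrow = nd)
  mat <- apply(mat, 2L, shift_vec)
  arr <- array(mat, dim = n[perm])
  as.numeric(aperm(arr, order(perm)))
}

#' Dense Markov matrix of a transition model
#'
#' Materializes the linear transformation as a `size x size` matrix by
#' applying it to unit masses in each cell. Intended for small grids
#' (testing and brute-force path enumeration); every column sums to one.
#'
#' @param tm a transition model.
#' @param grid a [param_grid].
#' @param direction `"forward"` or `"backward"`.
#' @param t step index for time-dependent models.
#' @export
transition_matrix <- function(tm, grid, direction = "forward", t = 1L) {
  m <- matrix(0, grid$size, grid$size)
  for (j in seq_len(grid$size)) {
    e <- numeric(grid$size)
    e[j] <- 1 / grid$voxel
    m[, j] <- apply_transition_w(transition_at(tm, t), e, grid, direction, t) *
      grid$voxel
  }
  m
}
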