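# Parameter lattices and prior distributions.
#
# All inference in this package runs on a regular lattice of parameter
# values theta^(i). A `param_grid` stores the cell centers of each
# dimension together with the voxel size Delta_theta (the product of the
# per-dimension spacings); a `grid_dist` stores a probability density per
# voxel over the lattice, so that sum(weights) * voxel is the total
# probability mass ("norm") of the distribution.

#' Regular parameter lattice
#'
#' Discretizes one or more parameter intervals into `n` cells each. Grid
#' values are cell midpoints, so the bounds themselves are never
#' evaluated: `]lower, upper[` with `n` cells has centers
#' `lower + (i + 1/2) * (upper - lower) / n`, `i = 0, ..., n-1`. This
#' keeps improper prior densities such as `1/sqrt(lambda)` away from
#' their singular endpoints. Multi-dimensional grids are Cartesian
#' products of the per-dimension center sets.
#'
#' @param lower,upper numeric vectors of interval bounds, one entry per
#'   parameter dimension (`lower < upper` elementwise).
#' @param n integer vector of cells per dimension (`>= 1`).
#' @param names character vector of parameter names.
#' @return An object of class `param_grid` with elements `dim_names`,
#'   `centers` (list of strictly increasing midpoint vectors), `delta`
#'   (per-dimension spacing), `voxel` (`prod(delta)`), `n`, and `size`
#'   (`prod(n)`).
#' @examples
#' g <- param_grid(0, 20, 1000, names = "kappa")
#' g$delta        # 0.02
#' g$centers[[1]][1]  # 0.01
#' @export
param_grid <- function(lower, upper, n, names = NULL) {
  k <- length(lower)
  if (length(upper) != k || length(n) != k) {
    stop_arg("n", "lower, upper and n must have equal length")
  }
  if (is.null(names)) names <- paste0("theta", seq_len(k))
  if (length(names) != k) stop_arg("names", "one name per dimension required")
  if (!is.numeric(lower) || !all(is.finite(lower))) {
    stop_arg("lower", "bounds must be finite")
  }
  if (!is.numeric(upper) || !all(is.finite(upper))) {
    stop_arg("upper", "bounds must be finite")
  }
  if (any(lower >= upper)) stop_arg("lower", "lower must be < upper")
  n <- as.integer(n)
  if (any(is.na(n)) || any(n < 1L)) stop_arg("n", "must be >= 1")
  delta <- (upper - lower) / n
  centers <- lapply(seq_len(k), function(d) {
    lower[d] + (seq_len(n[d]) - 0.5) * delta[d]
  })
  names(centers) <- names
  structure(
    list(
      dim_names = names, centers = centers, delta = delta,
      voxel = prod(delta), n = n, size = prod(n),
      lower = lower, upper = upper
    ),
    class = "param_grid"
  )
}

#' @export
print.param_grid <- function(x, ...) {
  cat("param_grid:", paste(
    sprintf(
      "%s in ]%g, %g[ (n = %d, spacing %g)",
      x$dim_names, x$lower, x$upper, x$n, x$delta
    ),
    collapse = " x "
  ), "\n")
  invisible(x)
}

# Expanded center coordinates of every lattice cell, in linearization
# order (first dimension fastest, matching R arrays).
#' @keywords internal
#' @noRd
grid_coords <- function(grid, dim = NULL) {
  if (!is.null(dim)) {
    d <- match(dim, grid$dim_names)
    if (is.na(d)) stop_arg("dim", paste("unknown dimension", dim))
    if (length(grid$n) == 1L) return(grid$centers[[1]])
    reps_inner <- prod(grid$n[seq_len(d - 1)])
    reps_outer <- grid$size / (reps_inner * grid$n[d])
    return(rep(rep(grid$centers[[d]], each = reps_inner), times = reps_outer))
  }
  ex <- do.call(expand.grid, c(grid$centers, KEEP.OUT.ATTRS = FALSE))
  names(ex) <- grid$dim_names
  ex
}

#' Distribution on a parameter lattice
#'
#' Bundles a lattice with a vector of non-negative densities (probability
#' per voxel). The norm of the distribution is `sum(w) * voxel`.
#'
#' @param grid a [param_grid].
#' @param w numeric vector of length `grid$size`, non-negative.
#' @return An object of class `grid_dist`.
#' @export
grid_dist <- function(grid, w) {
  stopifnot(inherits(grid, "param_grid"))
  if (length(w) != grid$size) stop_arg("w", "length must equal grid size")
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_arg("w", "weights must be finite and non-negative")
  }
  structure(list(grid = grid, w = as.numeric(w)), class = "grid_dist")
}

#' Total probability mass of a lattice distribution
#' @param dist a [grid_dist].
#' @return `sum(weights) * voxel`.
#' @export
grid_norm <- function(dist) {
  sum(dist$w) * dist$grid$voxel
}

#' Normalize a lattice distribution to unit mass
#' @param dist a [grid_dist].
#' @export
grid_normalize <- function(dist) {
  nrm <- grid_norm(dist)
  if (!is.finite(nrm) || nrm <= 0) {
    stop("cannot normalize a distribution with zero or non-finite mass")
  }
  grid_dist(dist$grid, dist$w / nrm)
}

#' Posterior mean of one parameter dimension
#' @param dist a [grid_dist] (any norm; means are computed on the
#'   normalized weights).
#' @param dim dimension name; defaults to the first.
#' @export
grid_mean <- function(dist, dim = NULL) {
  if (is.null(dim)) dim <- dist$grid$dim_names[1]
  th <- grid_coords(dist$grid, dim = dim)
  sum(th * dist$w) / sum(dist$w)
}

#' Marginal distribution of one dimension of a lattice distribution
#' @param dist a [grid_dist].
#' @param dim dimension name to keep.
#' @return A one-dimensional [grid_dist] on that dimension, with the same
#'   total mass as the input.
#' @export
grid_marginal <- function(dist, dim) {
  g <- dist$grid
  d <- match(dim, g$dim_names)
  if (is.na(d)) stop_arg("dim", paste("unknown dimension", dim))
  if (length(g$n) == 1L) return(dist)
  arr <- array(dist$w, dim = g$n)
  m <- apply(arr, d, sum) * g$voxel / g$delta[d]
  g1 <- param_grid(g$lower[d], g$upper[d], g$n[d], names = g$dim_names[d])
  grid_dist(g1, m)
}

#' Flat prior on a lattice
#'
#' Uniform, normalized density: every cell carries weight
#' `1 / (size * voxel)`.
#'
#' @param grid a [param_grid].
#' @return A normalized [grid_dist].
#' @export
flat_prior <- function(grid) {
  grid_dist(grid, rep(1 / (grid$size * grid$voxel), grid$size))
}

#' Jeffreys prior on a lattice
#'
#' Non-informative priors for the two scale-like low-level models used
#' here: `p(lambda) propto 1/sqrt(lambda)` for a Poisson rate and
#' `p(s) propto 1/s` for a Rayleigh mode. Both are improper on the half
#' line; on the finite lattice they are normalized over the truncated
#' support, which is what makes the model evidence well defined.
#'
#' @param grid a one-dimensional [param_grid] with strictly positive
#'   centers.
#' @param family `"poisson"` or `"rayleigh"`.
#' @return A normalized [grid_dist].
#' @export
jeffreys_prior <- function(grid, family = c("poisson", "rayleigh")) {
  family <- match.arg(family)
  if (length(grid$n) != 1L) {
    stop_arg("grid", "Jeffreys prior is defined here for 1-D grids")
  }
  th <- grid$centers[[1]]
  if (any(th <= 0)) {
    stop_arg("grid", "all centers must be > 0 (improper density undefined at 0)")
  }
  w <- switch(family, poisson = 1 / sqrt(th), rayleigh = 1 / th)
  grid_normalize(grid_dist(grid, w))
}

#' @export
print.grid_dist <- function(x, ...) {
  cat(
    sprintf(
      "grid_dist on %s (%d cells), norm = %.6g\n",
      paste(x$grid$dim_names, collapse = " x "), x$grid$size, grid_norm(x)
    )
  )
  invisible(x)
}
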