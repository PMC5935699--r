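# Low-level (observation) models.
#
# An observation model couples a parameter lattice with a factorized
# likelihood: for each data point d_t it returns the vector
# L_t^(i) = p(d_t | theta^(i), d_{t-1}) over the lattice. Auto-regressive
# models additionally condition on the previous data point; models with
# independent observations ignore it.

new_obs_model <- function(kind, grid, extra = list(), depends_on_prev = FALSE) {
  structure(
    c(list(kind = kind, grid = grid, depends_on_prev = depends_on_prev), extra),
    class = c(paste0("obs_", kind), "obs_model")
  )
}

#' Likelihood vector of one data point over the parameter lattice
#'
#' @param obs an observation model (`obs_poisson()`, `obs_gaussian_mean()`,
#'   `obs_vonmises()`, `obs_rayleigh()`, `obs_ar1()`).
#' @param d the data point.
#' @param t time-step index (used by models with per-step auxiliary data
#'   such as a known noise level).
#' @param d_prev previous data point, for auto-regressive models.
#' @return Numeric vector of length `obs$grid$size`, non-negative.
#' @export
likelihood <- function(obs, d, t = 1L, d_prev = NULL) {
  UseMethod("likelihood")
}

#' Poisson count model
#'
#' `L^(i) = lambda_i^k exp(-lambda_i) / k!` for a non-negative integer
#' count `k`, evaluated in log space for numerical safety at large counts.
#'
#' @param grid one-dimensional lattice of rates `lambda > 0`.
#' @return An `obs_model`.
#' @export
obs_poisson <- function(grid) {
  stopifnot(inherits(grid, "param_grid"), length(grid$n) == 1L)
  if (any(grid$centers[[1]] <= 0)) stop_arg("grid", "rates must be > 0")
  new_obs_model("poisson", grid)
}

#' @export
likelihood.obs_poisson <- function(obs, d, t = 1L, d_prev = NULL) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0 ||
      d != round(d)) {
    stop_arg("d", "count must be a non-negative integer")
  }
  stats::dpois(d, obs$grid$centers[[1]])
}

#' Gaussian model for a noisy mean with known noise level
#'
#' `L^(i) = dnorm(m, mu_i, sigma_t)` where the per-step standard
#' deviation `sigma_t` is known (e.g. a reconstruction standard error).
#'
#' @param grid one-dimensional lattice of means `mu`.
#' @param sigma known standard deviation: a scalar, or a vector indexed
#'   by time step.
#' @export
obs_gaussian_mean <- function(grid, sigma) {
  stopifnot(inherits(grid, "param_grid"), length(grid$n) == 1L)
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop_arg("sigma", "known standard deviation(s) must be > 0")
  }
  new_obs_model("gaussian_mean", grid, list(sigma = sigma))
}

#' @export
likelihood.obs_gaussian_mean <- function(obs, d, t = 1L, d_prev = NULL) {
  s <- if (length(obs$sigma) == 1L) obs$sigma else obs$sigma[[t]]
  if (!is.finite(s) || s <= 0) stop_arg("sigma", sprintf("missing at step %d", t))
  stats::dnorm(d, mean = obs$grid$centers[[1]], sd = s)
}

#' Von Mises model for turning angles
#'
#' `L^(i) = exp(kappa_i cos(phi)) / (2 pi I0(kappa_i))`, centered at
#' zero. The concentration `kappa` measures directional persistence:
#' `kappa = 0` is an isotropic random walk, large `kappa` near-ballistic
#' motion. `I0` is evaluated with exponential scaling so large `kappa`
#' does not overflow.
#'
#' @param grid one-dimensional lattice of concentrations `kappa > 0`.
#' @export
obs_vonmises <- function(grid) {
  stopifnot(inherits(grid, "param_grid"), length(grid$n) == 1L)
  if (any(grid$centers[[1]] <= 0)) stop_arg("grid", "kappa must be > 0")
  new_obs_model("vonmises", grid)
}

#' @export
likelihood.obs_vonmises <- function(obs, d, t = 1L, d_prev = NULL) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d)) {
    stop_arg("d", "turning angle must be finite")
  }
  k <- obs$grid$centers[[1]]
  # besselI(..., expon.scaled) returns exp(-k) I0(k); combining in log
  # space keeps the ratio finite for kappa up to the hundreds.
  exp(k * (cos(d) - 1) - log(besselI(k, 0, expon.scaled = TRUE))) / (2 * pi)
}

#' Rayleigh model for step speeds
#'
#' `L^(i) = v exp(-v^2 / (2 s_i^2)) / s_i^2` with mode parameter `s`
#' (the most probable speed).
#'
#' @param grid one-dimensional lattice of modes `s > 0`.
#' @export
obs_rayleigh <- function(grid) {
  stopifnot(inherits(grid, "param_grid"), length(grid$n) == 1L)
  if (any(grid$centers[[1]] <= 0)) stop_arg("grid", "s must be > 0")
  new_obs_model("rayleigh", grid)
}

#' @export
likelihood.obs_rayleigh <- function(obs, d, t = 1L, d_prev = NULL) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0) {
    stop_arg("d", "speed must be >= 0")
  }
  s <- obs$grid$centers[[1]]
  d * exp(-d^2 / (2 * s^2)) / s^2
}

#' Scaled AR-1 model for log-returns
#'
#' The return process `r_t = rho_t r_{t-1} + sqrt(1 - rho_t^2) v_t e_t`
#' with standard-normal driving noise `e_t` has conditional density
#' `Normal(rho r_{t-1}, (1 - rho^2) v^2)`; `v` is the stationary
#' standard deviation (volatility) and `rho` the lag-1 correlation. The
#' lattice is two-dimensional over `(rho, v)`. The first step conditions
#' on `r_0 = 0`.
#'
#' @param grid two-dimensional lattice with dimensions named `rho`
#'   (`|rho| < 1`) and `v` (`> 0`), in that order.
#' @export
obs_ar1 <- function(grid) {
  stopifnot(inherits(grid, "param_grid"), length(grid$n) == 2L)
  if (any(abs(grid$centers[[1]]) >= 1)) stop_arg("grid", "|rho| must be < 1")
  if (any(grid$centers[[2]] <= 0)) stop_arg("grid", "v must be > 0")
  rho <- grid_coords(grid, dim = grid$dim_names[1])
  v <- grid_coords(grid, dim = grid$dim_names[2])
  new_obs_model(
    "ar1", grid,
    list(rho_flat = rho, vtilde_flat = sqrt(1 - rho^2) * v),
    depends_on_prev = TRUE
  )
}

#' @export
likelihood.obs_ar1 <- function(obs, d, t = 1L, d_prev = NULL) {
  if (is.null(d_prev)) d_prev <- 0
  stats::dnorm(d, mean = obs$rho_flat * d_prev, sd = obs$vtilde_flat)
}

# ---- deterministic data transforms ----------------------------------

#' Turning angles of a 2-D trajectory
#'
#' Two conventions are provided. `"relative"` (the default, and the one
#' the synthetic trajectory generator inverts) is the signed angle from
#' the previous movement vector `v_{t-1}` to the current one `v_t`, so a
#' zero-centered von Mises model expresses directional persistence.
#' `"increment"` is the orientation `atan2` of the vectorial difference
#' `v_t - v_{t-1}` of subsequent movements. Steps where the angle is
#' undefined (a zero movement vector, or a zero difference vector for
#' the increment convention) yield `NA`.
#'
#' @param xy two-column matrix of positions (micrometers), >= 3 rows.
#' @param convention `"relative"` or `"increment"`.
#' @return Numeric vector of `nrow(xy) - 2` angles in `[-pi, pi]`, with
#'   attribute `convention`.
#' @export
turning_angles <- function(xy, convention = c("relative", "increment")) {
  convention <- match.arg(convention)
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) stop_arg("xy", "need >= 3 positions for a turning angle")
  if (any(!is.finite(xy))) stop_arg("xy", "positions must be finite")
  v <- diff(xy)
  n <- nrow(v)
  prev <- v[-n, , drop = FALSE]
  cur <- v[-1, , drop = FALSE]
  if (convention == "relative") {
    cross <- prev[, 1] * cur[, 2] - prev[, 2] * cur[, 1]
    dot <- prev[, 1] * cur[, 1] + prev[, 2] * cur[, 2]
    phi <- atan2(cross, dot)
    phi[rowSums(prev^2) == 0 | rowSums(cur^2) == 0] <- NA_real_
  } else {
    dx <- cur[, 1] - prev[, 1]
    dy <- cur[, 2] - prev[, 2]
    phi <- atan2(dy, dx)
    phi[dx == 0 & dy == 0] <- NA_real_
  }
  attr(phi, "convention") <- convention
  phi
}

#' Speeds of a 2-D trajectory
#'
#' Per-step displacement magnitude divided by the frame interval.
#'
#' @param xy two-column matrix of positions (micrometers), >= 2 rows.
#' @param frame_min frame interval in minutes.
#' @return Numeric vector of `nrow(xy) - 1` speeds in micrometers per
#'   minute.
#' @export
speeds <- function(xy, frame_min = 5) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) stop_arg("xy", "need >= 2 positions for a speed")
  check_scalar(frame_min, "frame_min")
  sqrt(rowSums(diff(xy)^2)) / frame_min
}

#' Log-returns of a price series
#'
#' `r_t = log(s_t / s_{t-1})`.
#'
#' @param prices numeric vector of strictly positive prices.
#' @return Numeric vector of `length(prices) - 1` log-returns.
#' @export
log_returns <- function(prices) {
  if (!is.numeric(prices) || length(prices) < 2L) {
    stop_arg("prices", "need >= 2 prices")
  }
  if (any(!is.finite(prices)) || any(prices <= 0)) {
    stop_arg("prices", "prices must be finite and > 0")
  }
  diff(log(prices))
}
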