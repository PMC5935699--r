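# Seeded synthetic-data generators.
#
# Each generator emulates the statistical structure of one case study
# and returns the data together with a `truth` record (the full
# generating parameter paths), so that recovery tests can compare
# inferred against true values. A seed is mandatory and fully determines
# the output; no generator touches the caller's RNG state.

# Gaussian random walk reflected into ]lower, upper[ (reflection keeps
# the marginal drift symmetric within the lattice bounds).
#' @keywords internal
#' @noRd
reflected_walk <- function(start, sigma, n, lower, upper) {
  x <- numeric(n)
  x[1] <- start
  if (n > 1L) {
    steps <- stats::rnorm(n - 1L, 0, sigma)
    for (t in 2:n) {
      y <- x[t - 1L] + steps[t - 1L]
      # fold back into the interval
      width <- upper - lower
      y <- (y - lower) %% (2 * width)
      if (y > width) y <- 2 * width - y
      x[t] <- lower + y
    }
  }
  x
}

#' Simulate Poisson counts with a change-point and/or rate drift
#'
#' Counts are drawn per step from `Poisson(lambda_t)`. The rate path is
#' either given explicitly, or built from a two-segment specification:
#' rate `lambda1` before the change-point `t_cp`, `lambda2` after it,
#' with optional reflected Gaussian drift (`sigma_pre`, `sigma_post`)
#' inside `]0, 6[` — the default lattice bounds of the accident-rate
#' analysis.
#'
#' @param n number of steps.
#' @param seed mandatory RNG seed.
#' @param lambda explicit rate path (length `n`), or `NULL`.
#' @param lambda1,lambda2 segment rates when `lambda` is `NULL`.
#' @param t_cp change-point step: last step of the first segment.
#' @param sigma_pre,sigma_post drift magnitudes per segment.
#' @param bounds reflection interval for the drifting rate.
#' @return List with `counts` (integer vector) and `truth` (the rate
#'   path and the generating parameters).
#' @export
gen_poisson_counts <- function(n, seed, lambda = NULL,
                               lambda1 = 3, lambda2 = 1, t_cp = NULL,
                               sigma_pre = 0, sigma_post = 0,
                               bounds = c(0, 6)) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    if (is.null(lambda)) {
      if (is.null(t_cp)) t_cp <- n # single segment
      stopifnot(t_cp >= 1L, t_cp <= n)
      pre <- reflected_walk(lambda1, sigma_pre, t_cp, bounds[1], bounds[2])
      lambda <- pre
      if (t_cp < n) {
        post <- reflected_walk(lambda2, sigma_post, n - t_cp,
                               bounds[1], bounds[2])
        lambda <- c(pre, post)
      }
    }
    if (length(lambda) != n || any(lambda <= 0)) {
      stop_arg("lambda", "rate path must be positive and of length n")
    }
    counts <- stats::rpois(n, lambda)
    list(
      counts = counts,
      truth = list(lambda = lambda, t_cp = t_cp, seed = seed,
                   sigma_pre = sigma_pre, sigma_post = sigma_post)
    )
  })
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), mean zero.
#' @keywords internal
#' @noRd
rvonmises0 <- function(n, kappa) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- kappa[if (length(kappa) > 1L) i else 1L]
    if (k < 1e-8) {
      out[i] <- stats::runif(1, -pi, pi)
      next
    }
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    repeat {
      u1 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c0 <- k * (r - f)
      u2 <- stats::runif(1)
      if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
        u3 <- stats::runif(1)
        out[i] <- sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

#' Simulate a persistent 2-D random-walk trajectory
#'
#' Inverts the migration model: relative turning angles are von Mises
#' draws with concentration `kappa_t`, step speeds are Rayleigh draws
#' with mode `s_t` (micrometers per minute), and positions accumulate
#' the resulting displacement vectors at `frame_min`-minute intervals.
#' The angle convention matches `turning_angles(..., "relative")`.
#'
#' @param n number of steps (the trajectory has `n + 1` positions).
#' @param seed mandatory RNG seed.
#' @param kappa persistence path: scalar or vector of length `n - 1`
#'   (one value per turning angle).
#' @param s speed-mode path: scalar or vector of length `n`.
#' @param frame_min frame interval in minutes.
#' @return List with `xy` (matrix of positions, micrometers) and `truth`.
#' @export
gen_trajectory <- function(n, seed, kappa = 4, s = 0.5, frame_min = 5) {
  stopifnot(n >= 2L)
  kappa <- rep_len(kappa, n - 1L)
  s <- rep_len(s, n)
  if (any(kappa < 0) || any(s <= 0)) {
    stop_arg("kappa", "kappa must be >= 0 and s > 0")
  }
  with_seed(seed, {
    v <- s * sqrt(-2 * log(stats::runif(n))) # Rayleigh with mode s
    heading <- numeric(n)
    heading[1] <- stats::runif(1, -pi, pi)
    turns <- rvonmises0(n - 1L, kappa)
    if (n > 1L) heading[2:n] <- heading[1] + cumsum(turns)
    step_len <- v * frame_min
    xy <- rbind(
      c(0, 0),
      cbind(cumsum(step_len * cos(heading)), cumsum(step_len * sin(heading)))
    )
    colnames(xy) <- c("x_um", "y_um")
    list(
      xy = xy, frame_min = frame_min,
      truth = list(kappa = kappa, s = s, turns = turns, speeds = v,
                   seed = seed)
    )
  })
}

#' Simulate scaled AR-1 log-returns
#'
#' Exact recursion `r_t = rho_t r_{t-1} + sqrt(1 - rho_t^2) v_t e_t`
#' with standard-normal driving noise and `r_0 = 0`. Optional abrupt
#' `jumps` override the parameter paths from a given step onward,
#' emulating sudden regime changes.
#'
#' @param n number of returns.
#' @param seed mandatory RNG seed.
#' @param rho correlation path: scalar or length-`n` vector, `|rho| < 1`.
#' @param v volatility path: scalar or length-`n` vector, `> 0`.
#' @param jumps optional list of `list(t =, rho =, v =)`; each sets the
#'   parameters from step `t` onward (either entry may be `NULL` to
#'   keep the current value).
#' @return List with `returns` and `truth` (full parameter paths).
#' @export
gen_ar1_returns <- function(n, seed, rho = 0, v = 0.001, jumps = NULL) {
  stopifnot(n >= 1L)
  rho <- rep_len(rho, n)
  v <- rep_len(v, n)
  if (!is.null(jumps)) {
    for (jp in jumps) {
      idx <- jp$t:n
      if (!is.null(jp$rho)) rho[idx] <- jp$rho
      if (!is.null(jp$v)) v[idx] <- jp$v
    }
  }
  if (any(abs(rho) >= 1) || any(v < 0)) {
    stop_arg("rho", "|rho| < 1 and v >= 0 required")
  }
  with_seed(seed, {
    eps <- stats::rnorm(n)
    r <- numeric(n)
    r_prev <- 0
    for (t in seq_len(n)) {
      r[t] <- rho[t] * r_prev + sqrt(1 - rho[t]^2) * v[t] * eps[t]
      r_prev <- r[t]
    }
    list(returns = r, truth = list(rho = rho, v = v, eps = eps, seed = seed))
  })
}

#' Simulate annual temperature anomalies under a trend scenario
#'
#' The mean path is constant until the change-point `t1`, then follows
#' the scenario: `linear` adds `a` per year, `quadratic` adds
#' `(b (t - t1))^2` cumulatively (continuous at the change-point), and
#' `plateau` is linear between `t1` and `t2` and constant afterwards.
#' Observations are `mu_t + sigma_t * N(0, 1)` with known per-year noise
#' `sigma_t`.
#'
#' @param years integer vector of calendar years.
#' @param seed mandatory RNG seed.
#' @param scenario `"linear"`, `"quadratic"` or `"plateau"`.
#' @param t1 change-point year (last year of the constant segment).
#' @param a slope, degrees C per year (linear and plateau scenarios).
#' @param b quadratic coefficient (quadratic scenario).
#' @param t2 plateau onset year (plateau scenario).
#' @param mu0 baseline anomaly, degrees C.
#' @param sigma known per-year observation noise: scalar or vector.
#' @return List with `anomaly`, `sigma`, `years` and `truth` (`mu` path).
#' @export
gen_temperature <- function(years, seed,
                            scenario = c("linear", "quadratic", "plateau"),
                            t1, a = 0.01, b = 0.01, t2 = NULL,
                            mu0 = -0.3, sigma = 0.15) {
  scenario <- match.arg(scenario)
  n <- length(years)
  sigma <- rep_len(sigma, n)
  if (any(sigma <= 0)) stop_arg("sigma", "known noise must be > 0")
  mu <- scenario_mean_path(years, scenario, t1, a, b, t2, mu0)
  with_seed(seed, {
    anomaly <- mu + sigma * stats::rnorm(n)
    list(
      anomaly = anomaly, sigma = sigma, years = years,
      truth = list(mu = mu, scenario = scenario, t1 = t1, a = a, b = b,
                   t2 = t2, mu0 = mu0, seed = seed)
    )
  })
}

# Deterministic scenario mean paths, continuous at the change-points.
#' @keywords internal
#' @noRd
scenario_mean_path <- function(years, scenario, t1, a, b, t2, mu0) {
  n <- length(years)
  mu <- rep(mu0, n)
  after <- years > t1
  if (any(after)) {
    dt <- years[after] - t1
    mu[after] <- mu0 + switch(scenario,
      linear = a * dt,
      quadratic = (b * dt)^2,
      plateau = {
        if (is.null(t2)) stop_arg("t2", "plateau scenario needs t2")
        a * pmin(dt, t2 - t1)
      }
    )
  }
  mu
}
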