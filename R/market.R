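# Intra-day market-fluctuation analysis.
#
# Minute log-returns follow a scaled AR-1 process with time-varying
# lag-1 correlation rho and volatility v on a 2-D lattice. The
# high-level model composes a Gaussian random walk (gradual variation,
# kernel widths sigma_rho, sigma_v) with a minimal-probability floor
# p_min (abrupt jumps). Each trading day is analyzed independently by a
# hyper-study over all (sigma_rho, sigma_v, p_min) combinations; the
# per-step hyper-averaged smoothed posteriors of all days are summed
# into the pooled joint (rho, v) distribution, whose marginals are then
# summarized by analytic fits: a Laplace distribution for rho and a
# compound-gamma distribution for v. An online two-model selector
# (normal versus memoryless dynamics) flags anomalous minutes.

#' Configuration for the market study
#'
#' Defaults are the published analysis: 100 x 400 lattice over
#' `rho in ]-1, 1[` and `v in ]0, 0.006[`; 10 kernel widths
#' `sigma_rho in [0, 0.15]`, 20 widths `sigma_v in [0, 1.5e-4]` and
#' `p_min in {0, 1e-6, 1e-3}` (600 combinations, equal prior); online
#' model priors 389/390 versus 1/390 with a 5 percent anomaly
#' threshold.
#'
#' @param n_rho,n_v lattice sizes.
#' @param v_max upper volatility bound.
#' @param n_sigma_rho,sigma_rho_max,n_sigma_v,sigma_v_max hyper-grids.
#' @param p_min_values minimal-probability floor values.
#' @param online_prior per-step prior `c(normal, chaotic)`.
#' @param threshold online anomaly threshold.
#' @export
market_config <- function(n_rho = 100, n_v = 400, v_max = 0.006,
                          n_sigma_rho = 10, sigma_rho_max = 0.15,
                          n_sigma_v = 20, sigma_v_max = 15e-5,
                          p_min_values = c(0, 1e-6, 1e-3),
                          online_prior = c(normal = 389 / 390,
                                           chaotic = 1 / 390),
                          threshold = 0.05) {
  list(
    n_rho = n_rho, n_v = n_v, v_max = v_max,
    n_sigma_rho = n_sigma_rho, sigma_rho_max = sigma_rho_max,
    n_sigma_v = n_sigma_v, sigma_v_max = sigma_v_max,
    p_min_values = p_min_values, online_prior = online_prior,
    threshold = threshold
  )
}

#' @keywords internal
#' @noRd
market_grid <- function(config) {
  param_grid(c(-1, 0), c(1, config$v_max), c(config$n_rho, config$n_v),
             names = c("rho", "v"))
}

#' @keywords internal
#' @noRd
market_hyper <- function(config) {
  expand.grid(
    sigma_rho = seq(0, config$sigma_rho_max,
                    length.out = config$n_sigma_rho),
    sigma_v = seq(0, config$sigma_v_max, length.out = config$n_sigma_v),
    p_min = config$p_min_values,
    KEEP.OUT.ATTRS = FALSE
  )
}

#' @keywords internal
#' @noRd
market_trans_factory <- function(eta) {
  parts <- list()
  if (eta$sigma_rho > 0 || eta$sigma_v > 0) {
    parts <- c(parts, list(trans_gaussian_rw(c(eta$sigma_rho, eta$sigma_v))))
  }
  if (!is.null(eta$p_min) && eta$p_min > 0) {
    parts <- c(parts, list(trans_minimal_prob(eta$p_min)))
  }
  if (length(parts) == 0L) trans_identity()
  else if (length(parts) == 1L) parts[[1]]
  else trans_compose(parts)
}

#' Market study: time-varying correlation and volatility
#'
#' Analyzes a set of trading days (minute closing prices) and pools the
#' per-minute parameter posteriors.
#'
#' @param days list of numeric price vectors, one per trading day
#'   (>= 2 prices each).
#' @param config a [market_config()].
#' @param fit_marginals if `TRUE`, fit the Laplace / compound-gamma
#'   summaries to the pooled marginals.
#' @param online if `TRUE`, run the online anomaly selector over each
#'   day.
#' @return List with `pooled` (joint [grid_dist] summed over all
#'   minutes and days, normalized), `rho_marginal`, `v_marginal`,
#'   `laplace_fit`, `cgamma_fit`, `mean_paths` (per day: rho and v
#'   mean-path matrices), `anomalies` (per day: flagged minutes), and
#'   the per-day hyper studies.
#' @export
market_study <- function(days, config = market_config(),
                         fit_marginals = TRUE, online = FALSE) {
  stopifnot(is.list(days), length(days) >= 1L)
  grid <- market_grid(config)
  obs <- obs_ar1(grid)
  prior <- flat_prior(grid)
  hyper <- market_hyper(config)

  pooled_w <- numeric(grid$size)
  n_minutes <- 0L
  studies <- vector("list", length(days))
  mean_paths <- vector("list", length(days))
  anomalies <- vector("list", length(days))
  for (d in seq_along(days)) {
    r <- log_returns(days[[d]])
    st <- hyper_study(r, obs, market_trans_factory, hyper, prior,
                      keep = "smoothed")
    avg <- averaged_posterior(st)
    pooled_w <- pooled_w + colSums(avg)
    n_minutes <- n_minutes + nrow(avg)
    mean_paths[[d]] <- cbind(
      rho = as.numeric(avg %*% obs$rho_flat) * grid$voxel,
      v = as.numeric(avg %*% grid_coords(grid, "v")) * grid$voxel
    )
    st$smoothed_runs <- NULL # drop the bulky per-run states
    studies[[d]] <- st
    if (online) {
      sel <- online_init(obs, prior, market_trans_factory,
                         hyper[hyper$p_min == 0, , drop = FALSE],
                         model_prior = config$online_prior)
      anomalies[[d]] <- online_run(sel, r, threshold = config$threshold)
    }
  }
  pooled <- grid_normalize(grid_dist(grid, pooled_w))
  rho_marginal <- grid_marginal(pooled, "rho")
  v_marginal <- grid_marginal(pooled, "v")

  out <- list(
    pooled = pooled, rho_marginal = rho_marginal, v_marginal = v_marginal,
    mean_paths = mean_paths, studies = studies, anomalies = anomalies,
    n_minutes = n_minutes, config = config
  )
  if (fit_marginals) {
    out$laplace_fit <- fit_laplace(rho_marginal)
    out$cgamma_fit <- fit_compound_gamma(v_marginal)
  }
  out
}

# ---- analytic marginal fits -----------------------------------------

#' Laplace fit to a lattice marginal
#'
#' Maximum likelihood on the lattice: the location is the weighted
#' median, the scale the weighted mean absolute deviation.
#'
#' @param marginal one-dimensional [grid_dist].
#' @return List with `location` and `scale`.
#' @export
fit_laplace <- function(marginal) {
  x <- marginal$grid$centers[[1]]
  p <- marginal$w / sum(marginal$w)
  cum <- cumsum(p)
  location <- x[which(cum >= 0.5)[1]]
  scale <- sum(p * abs(x - location))
  list(location = location, scale = scale)
}

#' Compound-gamma density
#'
#' `p(v) = integral G(v; alpha, p) G(p; beta, q) dp` with `G(x; a, b)`
#' the gamma density with shape `a` and inverse scale (rate) `b`; the
#' integral has the closed form
#' `q^beta v^(alpha-1) / B(alpha, beta) / (v + q)^(alpha+beta)` (a
#' scaled beta-prime density). Heavy-tailed: rare very large values
#' remain possible.
#'
#' @param v quantiles (> 0).
#' @param alpha,beta shapes; `q` inverse scale.
#' @param log if `TRUE`, return the log density.
#' @export
dcompound_gamma <- function(v, alpha, beta, q, log = FALSE) {
  ld <- beta * base::log(q) + (alpha - 1) * base::log(v) -
    lbeta(alpha, beta) - (alpha + beta) * base::log(v + q)
  if (log) ld else exp(ld)
}

#' Sample from the compound-gamma distribution
#'
#' Draws the inverse scale `p ~ Gamma(beta, rate = q)`, then
#' `v ~ Gamma(alpha, rate = p)`.
#'
#' @param n sample size.
#' @param alpha,beta,q parameters as in [dcompound_gamma()].
#' @export
rcompound_gamma <- function(n, alpha, beta, q) {
  p <- stats::rgamma(n, shape = beta, rate = q)
  stats::rgamma(n, shape = alpha, rate = p)
}

#' Compound-gamma fit to a lattice marginal
#'
#' Maximum likelihood over `(alpha, beta, q)` (log-parameterized
#' Nelder-Mead) of the lattice-weighted log density.
#'
#' @param marginal one-dimensional [grid_dist] on positive support.
#' @param init starting values.
#' @return List with `alpha`, `beta`, `q` and the optimizer record.
#' @export
fit_compound_gamma <- function(marginal, init = c(alpha = 2, beta = 2)) {
  x <- marginal$grid$centers[[1]]
  p <- marginal$w / sum(marginal$w)
  if (!"q" %in% names(init)) {
    init <- c(init, q = sum(p * x)) # data scale sets the scale of q
  }
  nll <- function(lpar) {
    par <- exp(lpar)
    -sum(p * dcompound_gamma(x, par[1], par[2], par[3], log = TRUE))
  }
  opt <- stats::optim(log(unlist(init)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  par <- exp(opt$par)
  list(alpha = par[[1]], beta = par[[2]], q = par[[3]], optim = opt)
}

#' Simulate returns from fitted marginal distributions
#'
#' Draws `(rho, v)` pairs from the fitted Laplace (truncated to
#' `]-1, 1[`) and compound-gamma marginals, generates an AR-1 return
#' series of length `len` for each pair, and pools the returns. The
#' fat tail of the pooled histogram relative to a single Gaussian is
#' the superstatistical signature of parameter fluctuations.
#'
#' @param n_series number of series.
#' @param len series length.
#' @param laplace list with `location`, `scale`.
#' @param cgamma list with `alpha`, `beta`, `q`.
#' @param seed RNG seed.
#' @return Numeric vector of pooled simulated returns.
#' @export
simulate_market_returns <- function(n_series, len, laplace, cgamma, seed) {
  with_seed(seed, {
    u <- stats::runif(n_series, -0.5, 0.5)
    rho <- laplace$location - laplace$scale * sign(u) * log(1 - 2 * abs(u))
    rho <- pmax(pmin(rho, 0.999), -0.999)
    v <- rcompound_gamma(n_series, cgamma$alpha, cgamma$beta, cgamma$q)
    out <- vector("list", n_series)
    for (i in seq_len(n_series)) {
      eps <- stats::rnorm(len)
      r <- numeric(len)
      r_prev <- 0
      sc <- sqrt(1 - rho[i]^2) * v[i]
      for (t in seq_len(len)) {
        r[t] <- rho[i] * r_prev + sc * eps[t]
        r_prev <- r[t]
      }
      out[[i]] <- r
    }
    unlist(out)
  })
}

#' Auto- and cross-correlation of daily-demeaned parameter paths
#'
#' Subtracts each day's average from its per-minute mean parameter
#' paths, then computes the auto-correlation of each parameter and the
#' cross-correlation between them as functions of lag (in minutes),
#' averaged over days. Positive cross-correlation lags compare future
#' volatility with current correlation.
#'
#' @param mean_paths list of per-day matrices with columns `rho`, `v`
#'   (as returned by [market_study()]).
#' @param max_lag largest lag, minutes.
#' @return List with `lag`, `acf_rho`, `acf_v`, `ccf` vectors.
#' @export
market_correlations <- function(mean_paths, max_lag = 120) {
  demean <- lapply(mean_paths, function(m) scale(m, scale = FALSE))
  rho_all <- lapply(demean, function(m) m[, "rho"])
  v_all <- lapply(demean, function(m) m[, "v"])
  lag_cor <- function(xs, ys, lag) {
    num <- 0
    n <- 0L
    for (d in seq_along(xs)) {
      x <- xs[[d]]
      y <- ys[[d]]
      len <- length(x) - abs(lag)
      if (len < 2L) next
      if (lag >= 0) {
        num <- num + sum(x[seq_len(len)] * y[seq_len(len) + lag])
      } else {
        num <- num + sum(x[seq_len(len) - lag] * y[seq_len(len)])
      }
      n <- n + len
    }
    sx <- sqrt(mean(unlist(xs)^2))
    sy <- sqrt(mean(unlist(ys)^2))
    num / n / (sx * sy)
  }
  lags <- 0:max_lag
  list(
    lag = lags,
    acf_rho = vapply(lags, function(l) lag_cor(rho_all, rho_all, l),
                     numeric(1)),
    acf_v = vapply(lags, function(l) lag_cor(v_all, v_all, l), numeric(1)),
    ccf = vapply(-max_lag:max_lag,
                 function(l) lag_cor(rho_all, v_all, l), numeric(1)),
    ccf_lag = -max_lag:max_lag
  )
}
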