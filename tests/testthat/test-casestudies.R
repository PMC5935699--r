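# Case-study pipelines on synthetic data (scaled-down grids where noted
# to keep the suite fast; the full published grids are the config
# defaults and are exercised by scripts/acceptance.R).

test_that("coal evidence factorization equals direct change-point runs", {
  # the pipeline computes p(d | t_cp, s_pre, s_post) as a product of an
  # independent prefix and suffix evidence; verify against a monolithic
  # engine run with a scheduled reset transition
  counts <- c(5, 3, 4, 6, 1, 0, 1, 2)
  g <- param_grid(0, 6, 25, names = "lambda")
  obs <- obs_poisson(g)
  prior <- jeffreys_prior(g, "poisson")
  for (case in list(list(t_cp = 3, s_pre = 0, s_post = 0),
                    list(t_cp = 5, s_pre = 0.4, s_post = 0.1),
                    list(t_cp = 2, s_pre = 0.8, s_post = 0))) {
    seg_pre <- gridbayes:::segment_log_evidence(counts, obs, prior, case$s_pre)
    seg_post <- gridbayes:::segment_log_evidence(counts, obs, prior, case$s_post)
    le_fact <- seg_pre$prefix[case$t_cp] + seg_post$suffix[case$t_cp + 1L]

    mk <- function(sig) if (sig > 0) trans_gaussian_rw(sig)
      else trans_identity()
    tm <- trans_schedule(function(t) {
      if (t == case$t_cp) trans_reset(prior)
      else if (t < case$t_cp) mk(case$s_pre)
      else mk(case$s_post)
    })
    fit <- gb_fit(counts, obs, tm, prior, smooth = FALSE,
                  keep_states = FALSE)
    expect_equal(le_fact, fit$log_evidence, tolerance = 1e-10)
  }
})

test_that("coal study recovers a synthetic change-point and is reproducible", {
  sim <- gen_poisson_counts(100, seed = 21, lambda1 = 3, lambda2 = 1,
                            t_cp = 60)
  cfg <- coal_config(n_lambda = 300, n_sigma = 1, sigma_max = 0,
                     years = 1:100, cp_years = 5:95)
  res <- coal_study(sim$counts, cfg)
  cp <- res$classic$cp_marginal
  expect_lte(abs(cp$year[which.max(cp$posterior)] - 60), 2)
  # pure function of (data, config): rerun is bit-identical
  res2 <- coal_study(sim$counts, cfg)
  expect_identical(res$classic$cp_marginal, res2$classic$cp_marginal)
  expect_identical(res$evidence_ratio, res2$evidence_ratio)
  # hyper-posteriors are normalized
  expect_equal(sum(res$fluctuation$hyper$posterior), 1, tolerance = 1e-10)
})

test_that("coal study rejects series with missing years", {
  cfg <- coal_config(years = 1852:1961)
  expect_error(coal_study(rep(1, 100), cfg), "one count per year")
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(year = 1852:1960, count = 1), tmp, row.names = FALSE)
  expect_error(read_count_series(tmp, years = 1852:1961), "1961")
})

test_that("climate study recovers a synthetic hockey stick and prefers the linear scenario", {
  # noise 0.06 degC chosen so the onset is identifiable to a few years;
  # reduced lattice (300 cells) and hyper-grids for test runtime
  years <- 1850:2001
  sim <- gen_temperature(years, seed = 31, scenario = "linear", t1 = 1937,
                         a = 0.01, mu0 = -0.2, sigma = 0.06)
  cfg <- climate_config(n_mu = 300, t1_window = c(1900, 1980),
                        n_slope = 21, horizon = 25)
  res <- climate_study(sim$anomaly, sim$sigma, years, cfg)

  tmarg <- res$linear$t1_marginal
  expect_lte(abs(tmarg$t1[which.max(tmarg$posterior)] - 1937), 5)
  smarg <- res$linear$slope_marginal
  expect_lte(abs(smarg$a[which.max(smarg$posterior)] - 0.01), 0.002)
  # linear-trend data: the linear scenario attains the largest weight
  expect_equal(names(which.max(res$model_prob)), "linear")
  # prediction reaches 25 years past the data with a sane mean
  expect_equal(res$prediction_year, 2026)
  truth_2026 <- -0.2 + 0.01 * (2026 - 1937)
  expect_lt(abs(res$linear$predictive_mean - truth_2026), 0.15)
  # category probabilities form a distribution
  expect_equal(sum(res$delta_categories), 1, tolerance = 1e-6)
})

test_that("with the slope grid collapsed to zero all scenarios give identical evidence", {
  years <- 1900:1960
  sim <- gen_temperature(years, seed = 35, scenario = "linear", t1 = 1930,
                         a = 0, sigma = 0.1)
  cfg <- climate_config(n_mu = 120, t1_window = c(1910, 1950),
                        n_slope = 1, slope_max = 0,
                        t2_window = c(1935, 1985), horizon = 10)
  res <- climate_study(sim$anomaly, sim$sigma, years, cfg)
  # every scenario reduces to the static-mean model
  expect_equal(res$linear$log_compound_evidence,
               res$quadratic$log_compound_evidence, tolerance = 1e-10)
  expect_equal(res$linear$log_compound_evidence,
               res$plateau$log_compound_evidence, tolerance = 1e-10)
})

# shared-latent or independent kappa/s paths for the migration checks
make_cell_tracks <- function(n_cells, n_steps, coupled, seed0) {
  walk01 <- function(seed, n) {
    gridbayes:::with_seed(seed, {
      z <- numeric(n)
      z[1] <- runif(1)
      for (t in 2:n) {
        y <- (z[t - 1] + rnorm(1, 0, 0.08)) %% 2
        z[t] <- if (y > 1) 2 - y else y
      }
      z
    })
  }
  lapply(seq_len(n_cells), function(i) {
    s1 <- seed0 + i
    z <- walk01(s1 * 7L, n_steps)
    z2 <- if (coupled) z else walk01(s1 * 13L + 1L, n_steps)
    tr <- gen_trajectory(n_steps, seed = s1,
                         kappa = 0.5 + 8 * z[-1], s = 0.08 + 0.7 * z2)
    list(cell_id = i, xy = tr$xy, frame_min = tr$frame_min)
  })
}

test_that("cell study detects persistence-speed co-movement and its absence", {
  cfg <- cell_config(n_kappa = 150, n_s = 150, n_sigma_kappa = 8,
                     n_sigma_s = 8, min_frames = 25,
                     min_displacement_um = 10)
  coupled <- suppressMessages(
    cell_study(make_cell_tracks(8, 60, TRUE, 400), cfg)
  )
  expect_gt(coupled$correlation, 0.3)

  # null construction (25 cells, scaled down from 50 for runtime)
  indep <- suppressMessages(
    cell_study(make_cell_tracks(25, 60, FALSE, 900), cfg)
  )
  expect_lt(abs(indep$correlation), 0.15)
})

test_that("a straight-line trajectory concentrates kappa in the top grid decile", {
  n <- 100
  xy <- cbind(2 * (0:n), numeric(n + 1)) # 2 um steps along x
  g <- param_grid(0, 20, 200, names = "kappa")
  fit <- gb_fit(as.numeric(turning_angles(xy)), obs_vonmises(g),
                trans_identity(), flat_prior(g))
  top <- g$centers[[1]] >= 18
  expect_gt(sum(fit$final$w[top]) * g$voxel, 0.99)
})

test_that("cell track filters drop short and sessile tracks with reasons", {
  cfg <- cell_config(min_frames = 25, min_displacement_um = 30)
  short <- matrix(rnorm(20), ncol = 2)
  expect_false(isTRUE(cell_track_ok(short, cfg)))
  expect_equal(attr(cell_track_ok(short, cfg), "reason"), "too short")
  sessile <- cbind(rnorm(30, sd = 0.5), rnorm(30, sd = 0.5))
  expect_equal(attr(cell_track_ok(sessile, cfg), "reason"),
               "insufficient displacement")
  runner <- cbind(seq(0, 60, length.out = 30), numeric(30))
  expect_true(isTRUE(cell_track_ok(runner, cfg)))
})

test_that("market study concentrates the pooled posterior at constant truth", {
  cfg <- market_config(n_rho = 50, n_v = 60, n_sigma_rho = 2,
                       sigma_rho_max = 0.05, n_sigma_v = 2,
                       sigma_v_max = 5e-5, p_min_values = c(0, 1e-3))
  days <- lapply(1:3, function(d) {
    sim <- gen_ar1_returns(200, seed = 80 + d, rho = -0.2, v = 0.002)
    100 * exp(cumsum(c(0, sim$returns)))
  })
  res <- market_study(days, cfg)
  expect_lt(abs(res$laplace_fit$location - (-0.2)), 0.05)
  expect_lt(abs(grid_mean(res$v_marginal, "v") - 0.002) / 0.002, 0.25)
  # pooled distribution is normalized and concentrated around truth
  expect_lt(abs(grid_norm(res$pooled) - 1), 1e-8)
  rho_sd <- sqrt(sum((res$rho_marginal$grid$centers[[1]] -
                        grid_mean(res$rho_marginal))^2 *
                     res$rho_marginal$w) * res$rho_marginal$grid$voxel)
  expect_lt(rho_sd, 0.3)
})

test_that("returns simulated from the published marginal fits are fat-tailed", {
  r <- simulate_market_returns(
    2000, 100,
    laplace = list(location = -0.047, scale = 0.077),
    cgamma = list(alpha = 10, beta = 6.2, q = 1.65e-4), seed = 5
  )
  kurt <- mean((r - mean(r))^4) / stats::sd(r)^4
  expect_gt(kurt, 3) # exceeds the Gaussian kurtosis
  expect_identical(r, simulate_market_returns(
    2000, 100, list(location = -0.047, scale = 0.077),
    list(alpha = 10, beta = 6.2, q = 1.65e-4), seed = 5
  ))
})

test_that("compound-gamma closed form matches numerical quadrature and sampling", {
  al <- 10; be <- 6.2; q <- 1.65e-4
  v <- c(5e-5, 2e-4, 1e-3)
  # numerical evaluation of the defining mixture integral
  ref <- vapply(v, function(vv) {
    # the integrand is proportional to a Gamma(al + be, vv + q) kernel
    # in p; integrate over that kernel's effective support
    lims <- stats::qgamma(c(1e-14, 1 - 1e-14), shape = al + be,
                          rate = vv + q)
    stats::integrate(function(p) {
      stats::dgamma(vv, shape = al, rate = p) *
        stats::dgamma(p, shape = be, rate = q)
    }, lims[1], lims[2], rel.tol = 1e-10)$value
  }, numeric(1))
  expect_rel_equal(dcompound_gamma(v, al, be, q), ref, 1e-6)
  # sampler moments: E[v] = alpha q / (beta - 1)
  s <- gridbayes:::with_seed(77, rcompound_gamma(2e5, al, be, q))
  expect_lt(abs(mean(s) - al * q / (be - 1)) / (al * q / (be - 1)), 0.02)
})

test_that("online selector flags exactly an injected one-minute volatility spike", {
  # a dramatic one-minute spike (30x volatility) on an otherwise calm
  # synthetic day; reduced lattice for runtime
  sim <- gen_ar1_returns(390, seed = 1, rho = 0, v = 0.001,
                         jumps = list(list(t = 200, v = 0.03),
                                      list(t = 201, v = 0.001)))
  g <- param_grid(c(-1, 0), c(1, 0.006), c(40, 60), names = c("rho", "v"))
  obs <- obs_ar1(g)
  hyper <- expand.grid(sigma_rho = seq(0, 0.15, length.out = 3),
                       sigma_v = seq(0, 15e-5, length.out = 3))
  fac <- function(eta) {
    if (eta$sigma_rho > 0 || eta$sigma_v > 0) {
      trans_gaussian_rw(c(eta$sigma_rho, eta$sigma_v))
    } else {
      trans_identity()
    }
  }
  sel <- online_init(obs, flat_prior(g), fac, hyper)
  res <- online_run(sel, sim$returns, threshold = 0.05)
  expect_identical(res$flagged, 200L)
  expect_gt(res$prob_chaotic[200], 0.99)
  # probability at the jump exceeds every other step
  expect_gt(res$prob_chaotic[200], max(res$prob_chaotic[-200]))
})
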