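test_that("two-cell worked example reproduces the hand-summed evidence", {
  g <- param_grid(0.5, 2.5, 2) # rate centers 1, 2; voxel 1
  prior <- flat_prior(g) # weights 1/2 each
  fit <- gb_fit(c(2, 0), obs_poisson(g), trans_identity(), prior)
  hand <- 0.5 * (dpois(2, 1) * dpois(0, 1) + dpois(2, 2) * dpois(0, 2))
  expect_equal(exp(fit$log_evidence), hand, tolerance = 1e-12)
  expect_equal(hand, 0.05216, tolerance = 1e-3)
})

test_that("single data point with identity transition reduces to Bayes normalization", {
  g <- param_grid(0, 6, 17)
  prior <- jeffreys_prior(g, "poisson")
  obs <- obs_poisson(g)
  fit <- gb_fit(3, obs, trans_identity(), prior)
  expect_equal(exp(fit$log_evidence),
               sum(likelihood(obs, 3) * prior$w) * g$voxel,
               tolerance = 1e-12)
})

test_that("evidence and smoothed posteriors match path enumeration across model combinations", {
  set.seed(2024)
  g5 <- param_grid(0, 6, 5)
  g7 <- param_grid(-2, 2, 7)
  cases <- list(
    list(obs = obs_poisson(g5), prior = jeffreys_prior(g5, "poisson"),
         data = c(4, 5, 1, 0, 2)),
    list(obs = obs_poisson(g5), prior = flat_prior(g5),
         data = c(0, 1, NA, 6)), # includes a missing point
    list(obs = obs_gaussian_mean(g7, sigma = c(0.5, 1, 0.7, 0.3, 1.2)),
         prior = flat_prior(g7), data = c(-0.5, 0.1, 0.4, NA, 1.0))
  )
  g5trans <- function(grid, prior) list(
    identity = trans_identity(),
    gaussian_rw = trans_gaussian_rw(1.5 * grid$delta),
    minimal_prob = trans_minimal_prob(1e-2),
    change_point = trans_schedule(function(t) {
      if (t == 2L) trans_reset(prior) else trans_gaussian_rw(grid$delta)
    }),
    shift = trans_shift(0.6 * grid$delta),
    composite = trans_compose(trans_gaussian_rw(grid$delta),
                              trans_minimal_prob(1e-3))
  )
  for (cs in cases) {
    for (tm in g5trans(cs$obs$grid, cs$prior)) {
      fit <- gb_fit(cs$data, cs$obs, tm, cs$prior)
      oracle <- oracle_paths(cs$data, cs$obs, tm, cs$prior)
      expect_rel_equal(exp(fit$log_evidence), oracle$evidence, 1e-10)
      expect_rel_equal(fit$smoothed, oracle$smoothed, 1e-9)
      # log evidence is the sum of the per-step increments
      expect_lt(abs(fit$log_evidence - sum(fit$log_increments)), 1e-10)
      # every stored posterior normalized
      norms <- rowSums(fit$smoothed) * cs$obs$grid$voxel
      expect_true(all(abs(norms - 1) <= 1e-8))
    }
  }
})

test_that("AR-1 evidence matches path enumeration on a tiny joint lattice", {
  g <- param_grid(c(-1, 0), c(1, 0.01), c(3, 2), names = c("rho", "v"))
  obs <- obs_ar1(g)
  prior <- flat_prior(g)
  set.seed(31)
  r <- as.numeric(arima.sim(list(ar = 0.4), 4, sd = 0.003))
  for (tm in list(trans_identity(),
                  trans_gaussian_rw(c(0.2, 0.002)),
                  trans_minimal_prob(1e-3))) {
    fit <- gb_fit(r, obs, tm, prior)
    oracle <- oracle_paths(r, obs, tm, prior)
    expect_rel_equal(exp(fit$log_evidence), oracle$evidence, 1e-10)
    expect_rel_equal(fit$smoothed, oracle$smoothed, 1e-9)
  }
})

test_that("identity-transition Poisson evidence approaches the gamma-Poisson marginal", {
  # conjugate oracle: with a Gamma(a, b) prior, the marginal likelihood
  # of counts k_1..k_T is b^a Gamma(a + K) / (Gamma(a) prod(k!) (b + T)^(a + K))
  a <- 2; b <- 1
  k <- c(3, 1, 4, 2, 2, 0, 5)
  K <- sum(k); T_ <- length(k)
  log_marg <- a * log(b) + lgamma(a + K) - lgamma(a) -
    sum(lgamma(k + 1)) - (a + K) * log(b + T_)

  g <- param_grid(0, 30, 4000) # support wide enough for negligible tail mass
  dens <- dgamma(g$centers[[1]], shape = a, rate = b)
  prior <- grid_normalize(grid_dist(g, dens))
  fit <- gb_fit(k, obs_poisson(g), trans_identity(), prior,
                smooth = FALSE, keep_states = FALSE)
  expect_rel_equal(exp(fit$log_evidence), exp(log_marg), 1e-3)
})

test_that("per-step renormalization does not change the evidence", {
  # unnormalized reference run on a short series: multiply likelihoods
  # and kernel applications without rescaling
  g <- param_grid(0, 6, 6)
  obs <- obs_poisson(g)
  prior <- jeffreys_prior(g, "poisson")
  tm <- trans_gaussian_rw(0.4)
  k <- c(2, 4, 1, 3)
  w <- prior$w
  for (t in seq_along(k)) {
    if (t > 1) w <- apply_transition(tm, grid_dist(g, w))$w
    w <- w * likelihood(obs, k[t])
  }
  ref <- sum(w) * g$voxel
  fit <- gb_fit(k, obs, tm, prior)
  expect_rel_equal(exp(fit$log_evidence), ref, 1e-12)
})

test_that("missing data at the series end never changes the evidence", {
  g <- param_grid(0, 6, 30)
  obs <- obs_poisson(g)
  prior <- jeffreys_prior(g, "poisson")
  for (tm in list(trans_identity(), trans_gaussian_rw(0.3),
                  trans_minimal_prob(1e-3))) {
    f0 <- gb_fit(c(2, 3, 1), obs, tm, prior)
    f1 <- gb_fit(c(2, 3, 1, NA, NA, NA), obs, tm, prior)
    expect_lt(abs(f0$log_evidence - f1$log_evidence), 1e-10)
  }
})

test_that("prediction propagates the final posterior through empty slots", {
  g <- param_grid(0, 6, 40)
  obs <- obs_poisson(g)
  prior <- jeffreys_prior(g, "poisson")
  fit <- gb_fit(c(2, 3, 1, 2), obs, trans_identity(), prior)

  # identity transition: every predictive distribution equals the final
  pd <- predict(fit, 5, trans_identity())
  for (p in pd) expect_equal(p$w, fit$final$w, tolerance = 1e-12)

  # diffusive transition: predictive variance non-decreasing in horizon
  pd2 <- predict(fit, 3, trans_gaussian_rw(0.2))
  vr <- vapply(pd2, function(p) {
    m <- grid_mean(p)
    sum((g$centers[[1]] - m)^2 * p$w) * g$voxel / sum(p$w * g$voxel)
  }, numeric(1))
  expect_true(all(diff(vr) > -1e-12))

  # trailing missing slots reproduce predict() under the same dynamics
  rw <- trans_gaussian_rw(0.2)
  fit3 <- gb_fit(c(2, 3, 1, 2), obs, rw, prior)
  fit4 <- gb_fit(c(2, 3, 1, 2, NA, NA), obs, rw, prior)
  pd3 <- predict(fit3, 2, rw)
  expect_rel_equal(fit4$filtered[6, ], grid_normalize(pd3[[2]])$w, 1e-10)
})

test_that("mean paths are the lattice-weighted means", {
  g <- param_grid(0, 5, 5)
  obs <- obs_poisson(g)
  fit <- gb_fit(c(2, 2), obs, trans_identity(), flat_prior(g))
  th <- g$centers[[1]]
  hand <- sum(th * fit$smoothed[1, ]) * g$voxel
  expect_equal(mean_path(fit)[1], hand, tolerance = 1e-12)

  # delta posterior has mean at its support point
  w <- numeric(5); w[3] <- 1 / g$voxel
  expect_equal(grid_mean(grid_dist(g, w)), th[3])
  # symmetric posterior on a symmetric grid
  gs <- param_grid(-1, 1, 9)
  ws <- dnorm(gs$centers[[1]], 0, 0.3)
  expect_equal(grid_mean(grid_dist(gs, ws)), 0, tolerance = 1e-12)
})

test_that("impossible data raise an error naming the step", {
  g <- param_grid(0, 1e-4, 3) # rates so small that a huge count underflows
  obs <- obs_poisson(g)
  expect_error(gb_fit(c(1, 500), obs, trans_identity(), flat_prior(g)),
               "step 2")
})
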