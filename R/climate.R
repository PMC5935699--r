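# Temperature-scenario analysis.
#
# Annual anomalies are Gaussian with known per-year noise sigma_t and an
# unknown mean mu on a lattice. Three high-level scenarios describe how
# mu evolves: constant until a change-point t1, then
#   linear:    mu increases by a per year,
#   quadratic: mu follows mu(t1) + (b (t - t1))^2,
#   plateau:   linear until a second change-point t2, constant after.
# All trend segments are realized as incremental deterministic shifts
# delta_t = f(t + 1) - f(t), so the mean path is continuous at the
# change-points. Prediction propagates the final posterior through empty
# data slots (default 25, reaching 2026 from data ending 2001).
#
# The hyper-grid over (t1, a | b, t2) is evaluated with shared
# structure: the identity segment before t1 is a single forward pass
# whose states are snapshotted at every candidate t1; each (t1, slope)
# continuation is advanced exactly once per pass; and because the
# dynamics after t2 are the identity, every plateau-onset evidence is
# read off during that advance as a pointwise product with cumulative
# likelihood products. An evidence pass (no state storage) is followed
# by a prediction pass restricted to the hyper combinations that carry
# essentially all posterior mass, keeping memory flat in the hyper-grid
# size.

#' Configuration for the temperature-scenario study
#'
#' Defaults are the published Australasia analysis: mean lattice
#' `]-1, 4[` degrees C with 15,000 cells (use `n_mu = 1500` as the fast
#' mode), change-point window 1825-2001, slope / coefficient lattice
#' `[0, 0.02]` per year with 50 values, plateau onset window 1950-2026,
#' 25-year prediction horizon.
#'
#' @param n_mu mean-lattice size.
#' @param mu_bounds lattice bounds, degrees C.
#' @param t1_window change-point year window (inclusive).
#' @param n_slope number of slope (and coefficient) values.
#' @param slope_max largest slope, degrees C per year.
#' @param t2_window plateau-onset window.
#' @param horizon number of empty prediction slots.
#' @param max_avg_combos cap on the number of hyper combinations kept
#'   for the model-averaged predictive distribution.
#' @export
climate_config <- function(n_mu = 15000, mu_bounds = c(-1, 4),
                           t1_window = c(1825, 2001),
                           n_slope = 50, slope_max = 0.02,
                           t2_window = c(1950, 2026),
                           horizon = 25, max_avg_combos = 2000) {
  list(
    n_mu = n_mu, mu_bounds = mu_bounds, t1_window = t1_window,
    n_slope = n_slope, slope_max = slope_max, t2_window = t2_window,
    horizon = horizon, max_avg_combos = max_avg_combos
  )
}

#' Temperature-scenario study with model averaging
#'
#' Fits the requested trend scenarios to an annual anomaly series with
#' known per-year noise, computes each scenario's compound evidence,
#' hyper-parameter marginals (change-point year, slope or coefficient,
#' plateau onset) and predictive distribution at the end of the
#' horizon, and averages the predictions with compound-evidence
#' weights.
#'
#' @param anomaly numeric vector of anomalies, degrees C.
#' @param sigma known per-year standard deviations (half the
#'   two-standard-error interval), same length.
#' @param years calendar years of the data.
#' @param config a [climate_config()].
#' @param scenarios subset of `c("linear", "quadratic", "plateau")`.
#' @return List with one entry per scenario (`hyper` table,
#'   `t1_marginal`, `slope_marginal`/`coef_marginal`, `t2_marginal`,
#'   `log_compound_evidence`, `predictive` final-year [grid_dist],
#'   `predictive_mean`, `predictive_sd`), plus `model_prob`,
#'   `averaged_predictive`, `delta_categories` (probabilities that the
#'   predicted change versus the last data year is below 0, in
#'   [0, 0.5), or at least 0.5 degrees C) and `prediction_year`.
#' @export
climate_study <- function(anomaly, sigma, years,
                          config = climate_config(),
                          scenarios = c("linear", "quadratic", "plateau")) {
  stopifnot(length(anomaly) == length(years), length(sigma) == length(years))
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop_arg("sigma", "known noise must be positive for every year")
  }
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  grid <- param_grid(config$mu_bounds[1], config$mu_bounds[2], config$n_mu,
                     names = "mu")
  obs <- obs_gaussian_mean(grid, sigma)
  prior <- flat_prior(grid)
  n <- length(anomaly)
  voxel <- grid$voxel

  liks <- lapply(seq_len(n), function(t) likelihood(obs, anomaly[t], t = t))
  t1_years <- years[years >= config$t1_window[1] & years <= config$t1_window[2]]
  t1_idx <- match(t1_years, years)
  slopes <- seq(0, config$slope_max, length.out = config$n_slope)

  # shared constant-mean prefix: filtered states and cumulative log
  # evidence at every candidate t1
  pre_states <- matrix(NA_real_, length(t1_idx), grid$size)
  pre_logev <- numeric(length(t1_idx))
  w <- prior$w
  acc <- 0
  k <- 1L
  for (t in seq_len(max(t1_idx))) {
    w <- w * liks[[t]]
    s <- sum(w) * voxel
    acc <- acc + log(s)
    w <- w / s
    if (k <= length(t1_idx) && t == t1_idx[k]) {
      pre_states[k, ] <- w
      pre_logev[k] <- acc
      k <- k + 1L
    }
  }

  # cumulative likelihood suffix products (log space) for the plateau
  # scenario: logB[t, ] = sum_{t' >= t} log L_t'
  logB <- NULL
  if ("plateau" %in% scenarios) {
    logB <- matrix(0, n + 1L, grid$size)
    for (t in n:1L) logB[t, ] <- logB[t + 1L, ] + log(pmax(liks[[t]], 1e-300))
  }

  res <- list()
  for (sc in scenarios) {
    res[[sc]] <- climate_one_scenario(
      sc, years, liks, grid, voxel, pre_states, pre_logev,
      t1_years, t1_idx, slopes, config, logB, n
    )
  }

  lc <- vapply(res, function(r) r$log_compound_evidence, numeric(1))
  model_prob <- exp(lc - logsumexp(lc))
  names(model_prob) <- names(res)

  avg_w <- Reduce(`+`, Map(function(r, p) r$predictive$w * p, res,
                           model_prob))
  averaged_predictive <- grid_dist(grid, avg_w)

  # predicted change versus the last data year, categorized using the
  # model-averaged mean of the last data year's posterior
  last_post <- Reduce(`+`, Map(function(r, p) r$last_posterior * p, res,
                               model_prob))
  mu_last <- sum(grid$centers[[1]] * last_post) * voxel
  dmu <- grid$centers[[1]] - mu_last
  pw <- avg_w * voxel
  delta_categories <- c(
    cooler = sum(pw[dmu < 0]),
    mild = sum(pw[dmu >= 0 & dmu < 0.5]),
    strong = sum(pw[dmu >= 0.5])
  )

  c(res, list(
    model_prob = model_prob,
    averaged_predictive = averaged_predictive,
    delta_categories = delta_categories,
    prediction_year = years[n] + config$horizon,
    grid = grid
  ))
}

#' @keywords internal
#' @noRd
climate_one_scenario <- function(sc, years, liks, grid, voxel,
                                 pre_states, pre_logev, t1_years, t1_idx,
                                 slopes, config, logB, n) {
  n_t1 <- length(t1_idx)
  n_a <- length(slopes)
  shift_by <- function(w, delta) {
    if (delta == 0) w else shift_dim(w, grid, 1L, delta)
  }
  # displacement applied in the transition from dt to dt + 1 years after
  # the change-point (dt = 0 leaves the change-point year itself)
  delta_at <- function(a, dt) {
    switch(sc,
      linear = ,
      plateau = a,
      quadratic = (a * (dt + 1))^2 - (a * dt)^2
    )
  }
  t2_years <- if (sc == "plateau") {
    seq(max(config$t2_window[1], years[2]), config$t2_window[2])
  } else NULL
  all_years <- c(years, (years[n] + 1L):(years[n] + config$horizon))

  # advance one (t1, slope) combination through the data years.
  # Returns the final state and evidence; when `t2_states` is TRUE,
  # also the per-candidate-t2 snapshot states and evidences needed by
  # the plateau scenario.
  advance <- function(i, j, t2_states = FALSE) {
    t1 <- t1_idx[i]
    w <- pre_states[i, ]
    acc <- pre_logev[i]
    snaps <- if (t2_states) list() else NULL
    if (t1 < n) {
      for (t in (t1 + 1L):n) {
        w <- shift_by(w, delta_at(slopes[j], t - 1L - t1))
        w <- w * liks[[t]]
        s <- sum(w) * voxel
        if (!is.finite(s) || s <= 0) {
          # the trend ran off the lattice: this hyper combination makes
          # the remaining data impossible
          acc <- -Inf
          break
        }
        acc <- acc + log(s)
        w <- w / s
        if (t2_states && years[t] %in% t2_years) {
          snaps[[as.character(years[t])]] <- list(w = w, acc = acc)
        }
      }
    }
    list(w = w, acc = acc, snaps = snaps)
  }

  # log evidence of a plateau model with onset year t2y, given the
  # snapshot state at t2 (identity dynamics afterwards)
  plateau_logev <- function(snap, t2) {
    if (t2 >= n) return(snap$acc)
    lb <- logB[t2 + 1L, ]
    m <- max(lb)
    snap$acc + log(sum(snap$w * exp(lb - m)) * voxel) + m
  }

  # ---- evidence pass (no state storage) ----
  rows <- list()
  for (i in seq_len(n_t1)) {
    for (j in seq_len(n_a)) {
      if (sc %in% c("linear", "quadratic")) {
        adv <- advance(i, j)
        rows[[length(rows) + 1L]] <- c(t1_years[i], slopes[j], adv$acc)
      } else {
        adv <- advance(i, j, t2_states = TRUE)
        for (t2y in t2_years) {
          if (t2y <= t1_years[i]) next
          t2 <- match(t2y, all_years)
          if (is.na(t2)) next
          snap <- if (t2 <= n) adv$snaps[[as.character(t2y)]] else NULL
          le <- if (t2 <= n) {
            if (is.null(snap)) -Inf else plateau_logev(snap, t2)
          } else {
            adv$acc # onset inside the horizon: all data on the trend
          }
          rows[[length(rows) + 1L]] <- c(t1_years[i], slopes[j], t2y, le)
        }
      }
    }
  }
  hyper <- as.data.frame(do.call(rbind, rows))
  names(hyper) <- if (sc == "plateau") c("t1", "a", "t2", "log_evidence")
    else c("t1", "a", "log_evidence")

  lp <- hyper$log_evidence - log(nrow(hyper)) # flat hyper-prior
  log_compound <- logsumexp(lp)
  hyper$posterior <- exp(lp - log_compound)

  marg <- function(col) {
    agg <- stats::aggregate(hyper$posterior, by = list(value = hyper[[col]]),
                            FUN = sum)
    names(agg) <- c(col, "posterior")
    agg[order(agg[[col]]), ]
  }

  # ---- prediction pass over the high-posterior combinations ----
  ord <- order(hyper$posterior, decreasing = TRUE)
  cum <- cumsum(hyper$posterior[ord])
  n_keep <- min(c(which(cum >= 0.9999), length(ord))[1],
                config$max_avg_combos)
  keep <- ord[seq_len(n_keep)]
  keep <- keep[hyper$posterior[keep] > 0]
  wnorm <- sum(hyper$posterior[keep])
  pred_acc <- numeric(grid$size)
  last_acc <- numeric(grid$size)
  kept <- hyper[keep, , drop = FALSE]
  kept$pr <- hyper$posterior[keep] / wnorm
  for (ij in split(kept, list(kept$t1, kept$a), drop = TRUE)) {
    i <- match(ij$t1[1], t1_years)
    j <- match(ij$a[1], slopes)
    t1 <- t1_idx[i]
    adv <- advance(i, j, t2_states = sc == "plateau")
    for (r in seq_len(nrow(ij))) {
      pr <- ij$pr[r]
      if (sc %in% c("linear", "quadratic")) {
        w_last <- adv$w
        wp <- w_last
        for (h in seq_len(config$horizon)) {
          wp <- shift_by(wp, delta_at(ij$a[r], n + h - 1L - t1))
        }
      } else {
        t2 <- match(ij$t2[r], all_years)
        if (t2 <= n) {
          snap <- adv$snaps[[as.character(ij$t2[r])]]
          if (t2 == n) {
            w_last <- snap$w
          } else {
            # posterior at the last data year under the plateau from t2
            lb <- logB[t2 + 1L, ]
            m <- max(lb)
            u <- snap$w * exp(lb - m)
            w_last <- u / (sum(u) * voxel)
          }
          wp <- w_last # identity dynamics through the horizon
        } else {
          w_last <- adv$w
          wp <- w_last
          for (h in seq_len(config$horizon)) {
            if ((n + h) <= t2) { # trend continues until the onset year
              wp <- shift_by(wp, delta_at(ij$a[r], n + h - 1L - t1))
            }
          }
        }
      }
      last_acc <- last_acc + w_last * pr
      pred_acc <- pred_acc + wp * pr
    }
  }
  predictive <- grid_dist(grid, pred_acc)
  mu <- grid$centers[[1]]
  pm <- sum(mu * pred_acc) * voxel
  psd <- sqrt(sum((mu - pm)^2 * pred_acc) * voxel)

  out <- list(
    hyper = hyper,
    log_compound_evidence = log_compound,
    t1_marginal = marg("t1"),
    predictive = predictive,
    predictive_mean = pm, predictive_sd = psd,
    last_posterior = last_acc
  )
  if (sc == "quadratic") out$coef_marginal <- marg("a")
  else out$slope_marginal <- marg("a")
  if (sc == "plateau") out$t2_marginal <- marg("t2")
  out
}
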