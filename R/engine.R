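# Forward-backward inference engine for one fixed high-level setting.
#
# Forward recursion: alpha_{t+1} = L_{t+1} * T(alpha_t), starting from
# the prior. The model evidence is the lattice sum of the final
# non-normalized posterior times the voxel size; accumulating it as
# per-step log normalization increments keeps 10^3-10^4 step series free
# of underflow. Backward recursion: beta_t = T'(L_{t+1} * beta_{t+1})
# with beta_N = 1; the smoothed posterior at t is proportional to
# alpha_t * beta_t. Missing data points (NA) contribute a flat improper
# likelihood factor L = 1 and therefore leave the evidence unchanged;
# trailing missing slots turn the run into a prediction.

#' Grid-based forward-backward inference
#'
#' Runs the iterative evidence accumulation and (optionally) the
#' backward smoothing recursion for a time series under one observation
#' model, one transition model and one prior.
#'
#' @param data numeric vector of data points; `NA` marks a missing or
#'   future (to be predicted) point.
#' @param obs an observation model (see [likelihood()]).
#' @param trans a transition model; the transition returned for step `t`
#'   acts between `t` and `t + 1`.
#' @param prior a normalized [grid_dist] on `obs$grid`; the prior is the
#'   parameter distribution at `t = 1` before the first likelihood
#'   factor.
#' @param smooth if `TRUE`, also run the backward recursion and store
#'   smoothed posteriors.
#' @param keep_states if `FALSE`, drop per-step posteriors and return
#'   only the evidence (memory-lean hyper-study inner loop).
#' @param d_prev0 value conditioned on as the "previous data point" of
#'   the first step for auto-regressive models.
#' @return An object of class `gb_fit` with elements `log_evidence`,
#'   `log_increments`, `filtered` and `smoothed` (step-by-cell matrices
#'   of normalized weights), `grid`, `final` (last filtered
#'   [grid_dist]).
#' @examples
#' g <- param_grid(0, 6, 100, names = "lambda")
#' fit <- gb_fit(c(4, 5, 1, 0), obs_poisson(g), trans_identity(),
#'               jeffreys_prior(g, "poisson"))
#' fit$log_evidence
#' @export
gb_fit <- function(data, obs, trans, prior, smooth = TRUE,
                   keep_states = TRUE, d_prev0 = 0) {
  stopifnot(inherits(obs, "obs_model"), inherits(trans, "transition"),
            inherits(prior, "grid_dist"))
  n_steps <- length(data)
  if (n_steps < 1L) stop_arg("data", "need at least one data point")
  grid <- obs$grid
  voxel <- grid$voxel
  if (abs(grid_norm(prior) - 1) > 1e-8) {
    stop_arg("prior", "must be normalized")
  }

  w <- prior$w
  log_inc <- numeric(n_steps)
  filtered <- if (keep_states) matrix(NA_real_, n_steps, grid$size) else NULL
  lik_at <- function(t) {
    if (is.na(data[t])) return(NULL) # flat improper factor
    d_prev <- if (!obs$depends_on_prev) NULL
      else if (t == 1L) d_prev0
      else if (is.na(data[t - 1L])) d_prev0
      else data[t - 1L]
    likelihood(obs, data[t], t = t, d_prev = d_prev)
  }

  for (t in seq_len(n_steps)) {
    if (t > 1L) {
      w <- apply_transition_w(transition_at(trans, t - 1L), w, grid,
                              "forward", t - 1L)
    }
    L <- lik_at(t)
    if (!is.null(L)) w <- w * L
    s <- sum(w) * voxel
    if (!is.finite(s) || s <= 0) {
      stop(sprintf(
        "posterior vanished at step %d: data point impossible under the model",
        t
      ))
    }
    log_inc[t] <- log(s)
    w <- w / s
    if (keep_states) filtered[t, ] <- w
  }

  smoothed <- NULL
  if (smooth && keep_states) {
    smoothed <- matrix(NA_real_, n_steps, grid$size)
    b <- rep(1, grid$size)
    smoothed[n_steps, ] <- filtered[n_steps, ]
    if (n_steps > 1L) {
      for (t in (n_steps - 1L):1L) {
        Lnext <- lik_at(t + 1L)
        u <- if (is.null(Lnext)) b else b * Lnext
        b <- apply_transition_w(transition_at(trans, t), u, grid,
                                "backward", t)
        b <- b / max(b) # scale-free: only alpha * beta matters
        sw <- filtered[t, ] * b
        smoothed[t, ] <- sw / (sum(sw) * voxel)
      }
    }
  }

  structure(
    list(
      log_evidence = sum(log_inc), log_increments = log_inc,
      filtered = filtered, smoothed = smoothed, grid = grid,
      n_steps = n_steps, data = data,
      final = grid_dist(grid, w)
    ),
    class = "gb_fit"
  )
}

#' @export
print.gb_fit <- function(x, ...) {
  cat(sprintf(
    "gb_fit: %d steps on %s grid (%d cells), log evidence = %.4f\n",
    x$n_steps, paste(x$grid$dim_names, collapse = " x "), x$grid$size,
    x$log_evidence
  ))
  invisible(x)
}

#' Per-step posterior of a fitted model as a lattice distribution
#'
#' @param fit a [gb_fit()] result with states kept.
#' @param t step index.
#' @param type `"smoothed"` (default) or `"filtered"`.
#' @export
posterior_at <- function(fit, t, type = c("smoothed", "filtered")) {
  type <- match.arg(type)
  m <- fit[[type]]
  if (is.null(m)) stop("fit does not store ", type, " posteriors")
  grid_dist(fit$grid, m[t, ])
}

#' Posterior mean path of one parameter dimension
#'
#' The per-step lattice mean `sum_i theta_i p(theta_i | .) * voxel` of
#' the smoothed (default) or filtered posteriors.
#'
#' @param fit a [gb_fit()] result with states kept.
#' @param dim dimension name; defaults to the first.
#' @param type `"smoothed"` or `"filtered"`.
#' @return Numeric vector of length `fit$n_steps`.
#' @export
mean_path <- function(fit, dim = NULL, type = c("smoothed", "filtered")) {
  type <- match.arg(type)
  m <- fit[[type]]
  if (is.null(m)) stop("fit does not store ", type, " posteriors")
  if (is.null(dim)) dim <- fit$grid$dim_names[1]
  th <- grid_coords(fit$grid, dim = dim)
  as.numeric(m %*% th) * fit$grid$voxel
}

#' Predictive parameter distributions
#'
#' Propagates the final filtered posterior through `horizon` empty data
#' slots: each future step applies the transition model only (its flat
#' improper likelihood factor adds no information and leaves the model
#' evidence unchanged).
#'
#' @param object a [gb_fit()] result.
#' @param horizon number of future steps (>= 1).
#' @param trans transition model for the future steps (the fit does not
#'   store its transition model, so it must be supplied).
#' @param ... unused.
#' @return List of `horizon` [grid_dist] objects.
#' @export
predict.gb_fit <- function(object, horizon, trans, ...) {
  stopifnot(horizon >= 1L, inherits(trans, "transition"))
  w <- object$final$w
  grid <- object$grid
  out <- vector("list", horizon)
  for (h in seq_len(horizon)) {
    t_idx <- object$n_steps + h - 1L
    w <- apply_transition_w(transition_at(trans, t_idx), w, grid,
                            "forward", t_idx)
    out[[h]] <- grid_dist(grid, w)
  }
  out
}
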