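# Online (per-step) model selection between two high-level models.
#
# Model A ("normal") propagates its forward states under regular
# dynamics, typically a Gaussian random walk over a hyper-grid of kernel
# widths; model B ("chaotic") resets to a flat prior at every step,
# discarding all previous parameter information. For each new data
# point, the one-point compound evidence of each model is the ratio of
# its compound evidence after and before the point; with fixed per-step
# prior probabilities p(A), p(B), the posterior probability of each
# model for the current point follows from Bayes' rule. A probability
# p(B | d_t) above a threshold flags the step as an anomaly: the moment
# at which previously accumulated parameter knowledge became useless.

#' Initialize an online two-model selector
#'
#' @param obs observation model shared by both high-level models.
#' @param prior normalized [grid_dist] initial prior for both models.
#' @param trans_factory `function(eta)` building the "normal" model's
#'   transition from one row of `hyper`.
#' @param hyper data frame of hyper-parameter combinations for the
#'   normal model (equal prior weight each).
#' @param model_prior fixed per-step prior probabilities
#'   `c(normal, chaotic)`; they are re-applied at every step rather than
#'   propagated.
#' @return An object of class `gb_online`.
#' @export
online_init <- function(obs, prior, trans_factory, hyper,
                        model_prior = c(normal = 389 / 390,
                                        chaotic = 1 / 390)) {
  stopifnot(inherits(obs, "obs_model"), inherits(prior, "grid_dist"),
            is.data.frame(hyper), nrow(hyper) >= 1L)
  if (length(model_prior) != 2L || any(model_prior <= 0)) {
    stop_arg("model_prior", "two positive probabilities required")
  }
  model_prior <- model_prior / sum(model_prior)
  trans <- lapply(seq_len(nrow(hyper)), function(j) {
    trans_factory(as.list(hyper[j, , drop = FALSE]))
  })
  structure(
    list(
      obs = obs, prior = prior, hyper = hyper, trans = trans,
      model_prior = model_prior,
      # per-eta forward states (weights) and running log-evidences of
      # the normal model
      states = replicate(nrow(hyper), prior$w, simplify = FALSE),
      log_ev = rep(0, nrow(hyper)),
      t = 0L, d_prev = 0,
      prob = c(normal = NA_real_, chaotic = NA_real_),
      prob_history = numeric(0)
    ),
    class = "gb_online"
  )
}

#' Advance the online selector by one data point
#'
#' Updates both models' forward states, computes each model's one-point
#' compound evidence (Eq. of the evidence ratio: evidence after the
#' point over evidence before it; for the memoryless model this is the
#' flat-prior average of the likelihood) and stores the posterior model
#' probabilities for the current point in `$prob` / `$prob_history`.
#'
#' @param state a `gb_online` object.
#' @param d new data point.
#' @return The updated state. `state$prob` sums to one by construction.
#' @export
online_step <- function(state, d) {
  stopifnot(inherits(state, "gb_online"))
  obs <- state$obs
  grid <- obs$grid
  voxel <- grid$voxel
  t_new <- state$t + 1L
  d_prev <- if (obs$depends_on_prev) state$d_prev else NULL
  L <- likelihood(obs, d, t = t_new, d_prev = d_prev)

  # normal model: advance each hyper-combination, accumulate evidence
  n_eta <- length(state$states)
  inc <- numeric(n_eta)
  for (j in seq_len(n_eta)) {
    w <- state$states[[j]]
    if (t_new > 1L) {
      w <- apply_transition_w(transition_at(state$trans[[j]], t_new - 1L),
                              w, grid, "forward", t_new - 1L)
    }
    w <- w * L
    s <- sum(w) * voxel
    if (!is.finite(s) || s <= 0) {
      stop(sprintf("normal-model posterior vanished at step %d", t_new))
    }
    inc[j] <- log(s)
    state$states[[j]] <- w / s
  }
  lp_before <- state$log_ev - log(n_eta)
  state$log_ev <- state$log_ev + inc
  lp_after <- state$log_ev - log(n_eta)
  log_ev_normal <- logsumexp(lp_after) - logsumexp(lp_before)

  # chaotic model: flat prior at every step, so its one-point evidence
  # is the flat average of the likelihood over the lattice
  log_ev_chaotic <- log(mean(L))

  lo <- c(log_ev_normal, log_ev_chaotic) + log(state$model_prior)
  p <- exp(lo - logsumexp(lo))
  names(p) <- c("normal", "chaotic")
  state$prob <- p
  state$prob_history <- c(state$prob_history, p[["chaotic"]])
  state$t <- t_new
  state$d_prev <- d
  state
}

#' Run the online selector over a whole series
#'
#' @param state a `gb_online` object (or the arguments of
#'   [online_init()] applied beforehand).
#' @param data numeric vector of data points.
#' @param threshold anomaly threshold on the per-step probability of the
#'   memoryless model.
#' @return List with `prob_chaotic` (per-step probability of the
#'   memoryless model), `flagged` (step indices with probability >=
#'   `threshold`) and the final state.
#' @export
online_run <- function(state, data, threshold = 0.05) {
  for (d in data) state <- online_step(state, d)
  p <- state$prob_history
  list(
    prob_chaotic = p,
    flagged = which(p >= threshold),
    state = state
  )
}
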