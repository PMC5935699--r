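# Hyper-parameter grid studies, model averaging, model comparison.
#
# A hyper-study runs the engine once per high-level parameter
# combination eta^(j). The compound model evidence marginalizes over the
# hyper-grid, p({d}) = sum_j p({d} | eta_j) p(eta_j); normalizing the
# summands instead yields the hyper-parameter posterior, which in turn
# weights model-averaged low-level posteriors.

#' Hyper-parameter grid study
#'
#' @param data numeric data vector (`NA` = missing).
#' @param obs observation model.
#' @param trans_factory `function(eta)` mapping one row of `hyper`
#'   (as a named list) to a transition model.
#' @param hyper data frame of hyper-parameter combinations, one row per
#'   candidate `eta^(j)` (e.g. from `expand.grid`).
#' @param prior normalized [grid_dist] initial prior.
#' @param hyper_prior numeric vector of prior weights over the rows of
#'   `hyper`; defaults to equal probability. Normalized internally.
#' @param keep `"none"` (evidence only), `"mean_path"` (accumulate the
#'   hyper-averaged smoothed mean path of each grid dimension), or
#'   `"smoothed"` (retain every run's smoothed posteriors; memory grows
#'   as runs x steps x cells).
#' @param d_prev0 see [gb_fit()].
#' @return An object of class `gb_hyper_study`: `hyper` with appended
#'   `log_evidence` and `posterior` columns, `log_compound_evidence`,
#'   and depending on `keep` the `mean_paths` matrix (steps x
#'   dimensions) or the list of per-run smoothed matrices.
#' @export
hyper_study <- function(data, obs, trans_factory, hyper, prior,
                        hyper_prior = NULL,
                        keep = c("none", "mean_path", "smoothed"),
                        d_prev0 = 0) {
  keep <- match.arg(keep)
  stopifnot(is.function(trans_factory), is.data.frame(hyper), nrow(hyper) >= 1L)
  m <- nrow(hyper)
  if (is.null(hyper_prior)) hyper_prior <- rep(1 / m, m)
  if (length(hyper_prior) != m || any(hyper_prior < 0)) {
    stop_arg("hyper_prior", "needs one non-negative weight per hyper row")
  }
  hyper_prior <- hyper_prior / sum(hyper_prior)

  log_ev <- numeric(m)
  runs <- if (keep == "smoothed") vector("list", m) else NULL
  mp_acc <- NULL
  mp_runs <- if (keep == "mean_path") vector("list", m) else NULL
  for (j in seq_len(m)) {
    eta <- as.list(hyper[j, , drop = FALSE])
    tm <- trans_factory(eta)
    fit <- gb_fit(data, obs, tm, prior,
                  smooth = keep != "none",
                  keep_states = keep != "none", d_prev0 = d_prev0)
    log_ev[j] <- fit$log_evidence
    if (keep == "smoothed") runs[[j]] <- fit$smoothed
    if (keep == "mean_path") {
      mp_runs[[j]] <- vapply(
        obs$grid$dim_names,
        function(dn) mean_path(fit, dim = dn),
        numeric(length(data))
      )
    }
  }

  lp <- log_ev + log(hyper_prior)
  log_compound <- logsumexp(lp)
  post <- exp(lp - log_compound)
  hyper$log_evidence <- log_ev
  hyper$posterior <- post

  if (keep == "mean_path") {
    # hyper-averaged mean path: means are linear in the posterior, so
    # averaging per-run mean paths with the hyper-posterior weights
    # equals the mean path of the model-averaged posterior
    mp_acc <- Reduce(`+`, Map(function(mp, p) mp * p, mp_runs, post))
    colnames(mp_acc) <- obs$grid$dim_names
  }

  structure(
    list(
      hyper = hyper, hyper_prior = hyper_prior,
      log_evidence = log_ev, posterior = post,
      log_compound_evidence = log_compound,
      mean_paths = mp_acc,
      smoothed_runs = runs,
      grid = obs$grid, n_steps = length(data), data = data
    ),
    class = "gb_hyper_study"
  )
}

#' @export
print.gb_hyper_study <- function(x, ...) {
  cat(sprintf(
    "gb_hyper_study: %d hyper combinations, log compound evidence = %.4f\n",
    nrow(x$hyper), x$log_compound_evidence
  ))
  best <- which.max(x$posterior)
  cat("  MAP hyper combination:\n")
  print(x$hyper[best, , drop = FALSE])
  invisible(x)
}

#' Marginal hyper-parameter posterior
#'
#' Sums the joint hyper-posterior of a study over all but one hyper
#' dimension.
#'
#' @param study a [hyper_study()] result.
#' @param name hyper-parameter column name.
#' @return Data frame with the unique values and their posterior mass.
#' @export
hyper_marginal <- function(study, name) {
  h <- study$hyper
  if (!name %in% names(h)) stop_arg("name", "unknown hyper-parameter")
  agg <- stats::aggregate(h$posterior, by = list(value = h[[name]]), FUN = sum)
  names(agg) <- c(name, "posterior")
  agg[order(agg[[name]]), , drop = FALSE]
}

#' Model-averaged smoothed posteriors
#'
#' The convex combination of per-run smoothed posteriors, weighted by
#' the hyper-parameter posterior. Requires `keep = "smoothed"`.
#'
#' @param study a [hyper_study()] result.
#' @return Matrix (steps x cells) of normalized weights.
#' @export
averaged_posterior <- function(study) {
  if (is.null(study$smoothed_runs)) {
    stop("hyper_study must be run with keep = \"smoothed\"")
  }
  Reduce(`+`, Map(function(sm, p) sm * p, study$smoothed_runs,
                  study$posterior))
}

#' Bayes-factor comparison of hyper-studies
#'
#' Normalized posterior model probabilities proportional to compound
#' evidence times model prior. All studies must be fitted to identical
#' data.
#'
#' @param studies named list of [hyper_study()] results.
#' @param model_prior prior probabilities (default equal).
#' @return Named numeric vector of posterior model probabilities.
#' @export
compare_models <- function(studies, model_prior = NULL) {
  stopifnot(is.list(studies), length(studies) >= 2L)
  d0 <- studies[[1]]$data
  for (s in studies[-1]) {
    if (!identical(length(s$data), length(d0)) ||
        !isTRUE(all.equal(s$data, d0))) {
      stop("studies were fitted to different data; comparison is meaningless")
    }
  }
  m <- length(studies)
  if (is.null(model_prior)) model_prior <- rep(1 / m, m)
  model_prior <- model_prior / sum(model_prior)
  lp <- vapply(studies, function(s) s$log_compound_evidence, numeric(1)) +
    log(model_prior)
  p <- exp(lp - logsumexp(lp))
  names(p) <- names(studies)
  p
}
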