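# Coal-mining disaster change-point analysis.
#
# Annual disaster counts are Poisson with a time-varying rate lambda.
# Two competing high-level models share a single change-point t_cp (the
# reset to the Jeffreys prior acts in the transition from t_cp to
# t_cp + 1):
#   * classic:   rate constant within each segment (sigma = 0),
#   * fluctuation: rate additionally drifts as a Gaussian random walk
#     with segment-specific magnitudes sigma_pre, sigma_post.
# Because the reset erases all parameter memory, the evidence factorizes
# exactly as
#   p(d | t_cp, s_pre, s_post) = E_pre(t_cp; s_pre) * E_post(t_cp; s_post)
# where E_pre(t; s) is the evidence of counts 1..t under drift s started
# from the Jeffreys prior and E_post(t; s) the evidence of counts
# t+1..N started fresh from the Jeffreys prior. One forward pass per
# sigma yields all prefix evidences; one backward (suffix) pass per
# sigma yields all suffix evidences. The full hyper-grid therefore costs
# 2 * n_sigma lattice sweeps instead of one per hyper combination.

#' Configuration for the coal-mining change-point study
#'
#' Defaults are the published analysis: rate lattice of 1000 cells on
#' `]0, 6[` per year, change-point restricted to years before 1921,
#' segment drift magnitudes on `[0, 1]` with 25 values (thin with
#' `n_sigma` for a fast mode), flat hyper-priors.
#'
#' @param n_lambda rate lattice size.
#' @param lambda_max upper rate bound (events per year).
#' @param n_sigma number of drift-magnitude values per segment.
#' @param sigma_max largest drift magnitude.
#' @param cp_years candidate change-point years (default: all data years
#'   before 1921).
#' @param years data years.
#' @export
coal_config <- function(n_lambda = 1000, lambda_max = 6,
                        n_sigma = 25, sigma_max = 1,
                        cp_years = NULL, years = 1852:1961) {
  list(
    n_lambda = n_lambda, lambda_max = lambda_max,
    n_sigma = n_sigma, sigma_max = sigma_max,
    years = years,
    cp_years = if (is.null(cp_years)) years[years < 1921] else cp_years
  )
}

# Cumulative log-evidence of prefixes (counts 1..t) and suffixes
# (counts t..N), each started from `prior` under a Gaussian random walk
# of magnitude sigma. The suffix pass runs the adjoint recursion
# u_t = L_t * T'(u_{t+1}) and reads off sum(prior * u_t) * voxel.
#' @keywords internal
#' @noRd
segment_log_evidence <- function(counts, obs, prior, sigma) {
  grid <- obs$grid
  voxel <- grid$voxel
  n <- length(counts)
  tm <- if (sigma > 0) trans_gaussian_rw(sigma) else trans_identity()
  liks <- lapply(seq_len(n), function(t) likelihood(obs, counts[t], t = t))

  pre <- numeric(n)
  w <- prior$w
  acc <- 0
  for (t in seq_len(n)) {
    if (t > 1L) w <- apply_transition_w(tm, w, grid, "forward", t - 1L)
    w <- w * liks[[t]]
    s <- sum(w) * voxel
    acc <- acc + log(s)
    pre[t] <- acc
    w <- w / s
  }

  suf <- numeric(n)
  u <- rep(1, grid$size)
  acc <- 0
  for (t in n:1L) {
    u <- u * liks[[t]]
    s <- sum(prior$w * u) * voxel
    suf[t] <- log(s) + acc
    if (t > 1L) {
      u <- apply_transition_w(tm, u, grid, "backward", t - 1L)
      m <- max(u)
      u <- u / m
      acc <- acc + log(m)
    }
  }
  list(prefix = pre, suffix = suf)
}

#' Coal-mining change-point study
#'
#' Runs the classic (piecewise-constant) and fluctuation (piecewise
#' drifting) change-point models on an annual disaster-count series and
#' compares their compound model evidence.
#'
#' @param counts integer vector of annual counts covering
#'   `config$years`; defaults to the bundled 1852-1961 disaster record.
#' @param config a [coal_config()].
#' @param mean_paths if `TRUE`, additionally compute the smoothed mean
#'   accident-rate path of each model, hyper-averaged over the
#'   combinations holding 99.9 percent of the hyper-posterior mass.
#' @return List with elements `classic` and `fluctuation` (each with
#'   `hyper` table, change-point marginal `cp_marginal`, log compound
#'   evidence), the segment-drift marginals `sigma_pre_marginal` /
#'   `sigma_post_marginal` of the fluctuation model, `evidence_ratio`
#'   (fluctuation over classic) and `model_prob`.
#' @export
coal_study <- function(counts = NULL, config = coal_config(),
                       mean_paths = FALSE) {
  years <- config$years
  if (is.null(counts)) {
    counts <- read_count_series(
      system.file("extdata", "coal_disasters_annual.csv",
                  package = "gridbayes"),
      years = years
    )
  }
  if (length(counts) != length(years)) {
    stop_arg("counts", sprintf("need one count per year (%d)", length(years)))
  }
  grid <- param_grid(0, config$lambda_max, config$n_lambda, names = "lambda")
  obs <- obs_poisson(grid)
  prior <- jeffreys_prior(grid, "poisson")
  sigmas <- seq(0, config$sigma_max, length.out = config$n_sigma)

  seg <- lapply(sigmas, function(s) segment_log_evidence(counts, obs, prior, s))
  cp_idx <- match(config$cp_years, years)
  n <- length(counts)

  # log evidence for every (t_cp, sigma_pre, sigma_post): prefix at the
  # change-point year plus suffix starting the year after
  combos <- expand.grid(
    cp = seq_along(cp_idx), i_pre = seq_along(sigmas),
    i_post = seq_along(sigmas), KEEP.OUT.ATTRS = FALSE
  )
  log_ev <- mapply(function(cp, ip, is_) {
    t <- cp_idx[cp]
    seg[[ip]]$prefix[t] +
      if (t < n) seg[[is_]]$suffix[t + 1L] else 0
  }, combos$cp, combos$i_pre, combos$i_post)

  hyper_fluct <- data.frame(
    t_cp = config$cp_years[combos$cp],
    sigma_pre = sigmas[combos$i_pre],
    sigma_post = sigmas[combos$i_post],
    log_evidence = log_ev
  )
  classic_rows <- combos$i_pre == 1L & combos$i_post == 1L
  stopifnot(sigmas[1] == 0)
  hyper_classic <- hyper_fluct[classic_rows,
                               c("t_cp", "log_evidence"), drop = FALSE]

  summarize <- function(h) {
    lp <- h$log_evidence - log(nrow(h)) # flat hyper-prior
    log_compound <- logsumexp(lp)
    h$posterior <- exp(lp - log_compound)
    cp <- stats::aggregate(h$posterior, by = list(year = h$t_cp), FUN = sum)
    names(cp) <- c("year", "posterior")
    list(hyper = h, log_compound_evidence = log_compound,
         cp_marginal = cp[order(cp$year), ])
  }
  classic <- summarize(hyper_classic)
  fluct <- summarize(hyper_fluct)

  marg <- function(col) {
    agg <- stats::aggregate(fluct$hyper$posterior,
                            by = list(value = fluct$hyper[[col]]), FUN = sum)
    names(agg) <- c(col, "posterior")
    agg[order(agg[[col]]), ]
  }

  ratio <- exp(fluct$log_compound_evidence - classic$log_compound_evidence)
  out <- list(
    classic = classic, fluctuation = fluct,
    sigma_pre_marginal = marg("sigma_pre"),
    sigma_post_marginal = marg("sigma_post"),
    evidence_ratio = ratio,
    model_prob = c(classic = 1 / (1 + ratio),
                   fluctuation = ratio / (1 + ratio)),
    years = years, counts = counts, config = config
  )

  if (mean_paths) {
    out$rate_path <- list(
      classic = coal_mean_path(counts, years, obs, prior, classic$hyper,
                               cp_idx = match(classic$hyper$t_cp, years)),
      fluctuation = coal_mean_path(counts, years, obs, prior, fluct$hyper,
                                   cp_idx = match(fluct$hyper$t_cp, years))
    )
  }
  out
}

# Hyper-averaged smoothed mean rate path, restricted to the hyper
# combinations carrying 99.9 percent of posterior mass (the remaining
# weight is renormalized over them).
#' @keywords internal
#' @noRd
coal_mean_path <- function(counts, years, obs, prior, hyper, cp_idx,
                           mass = 0.999) {
  ord <- order(hyper$posterior, decreasing = TRUE)
  keep <- ord[seq_len(which(cumsum(hyper$posterior[ord]) >= mass)[1])]
  wsum <- sum(hyper$posterior[keep])
  acc <- numeric(length(counts))
  for (r in keep) {
    t_cp <- cp_idx[r]
    make_seg <- function(sig) if (sig > 0) trans_gaussian_rw(sig)
      else trans_identity()
    pre_tm <- make_seg(if ("sigma_pre" %in% names(hyper)) hyper$sigma_pre[r]
                       else 0)
    post_tm <- make_seg(if ("sigma_post" %in% names(hyper)) hyper$sigma_post[r]
                        else 0)
    tm <- trans_schedule(function(t) {
      if (t == t_cp) trans_reset(prior)
      else if (t < t_cp) pre_tm
      else post_tm
    })
    fit <- gb_fit(counts, obs, tm, prior)
    acc <- acc + mean_path(fit) * hyper$posterior[r] / wsum
  }
  acc
}
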