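# Tumor-cell migration analysis.
#
# Each 2-D trajectory is reduced to a series of turning angles (von
# Mises low-level model with persistence kappa) and a series of step
# speeds (Rayleigh low-level model with mode s). Both parameters drift
# as Gaussian random walks whose magnitudes are determined per cell by
# a hyper-study; the mean parameter paths come from the model-averaged
# smoothed posteriors. Pooling the per-step means of all retained cells
# gives the persistence-speed correlation, the migratory signature that
# tracks 3-D invasiveness.

#' Configuration for the cell-migration study
#'
#' Defaults are the published analysis: kappa lattice `]0, 20[` with
#' 1000 cells and drift magnitudes `[0, 5]` with 50 values; speed-mode
#' lattice `]0, 1.5[` micrometers per minute with 1000 cells and drift
#' magnitudes `[0, 0.2]` with 50 values; tracks must span at least 2 h
#' of continuous 5-minute frames (>= 25 positions) and migrate at least
#' 30 micrometers from their starting position.
#'
#' @param n_kappa,kappa_max persistence lattice.
#' @param n_sigma_kappa,sigma_kappa_max persistence drift hyper-grid.
#' @param n_s,s_max speed-mode lattice (micrometers per minute).
#' @param n_sigma_s,sigma_s_max speed drift hyper-grid.
#' @param min_frames minimum number of consecutive positions.
#' @param min_displacement_um minimum maximal displacement from the
#'   starting position, micrometers.
#' @param angle_convention passed to [turning_angles()].
#' @export
cell_config <- function(n_kappa = 1000, kappa_max = 20,
                        n_sigma_kappa = 50, sigma_kappa_max = 5,
                        n_s = 1000, s_max = 1.5,
                        n_sigma_s = 50, sigma_s_max = 0.2,
                        min_frames = 25, min_displacement_um = 30,
                        angle_convention = "relative") {
  list(
    n_kappa = n_kappa, kappa_max = kappa_max,
    n_sigma_kappa = n_sigma_kappa, sigma_kappa_max = sigma_kappa_max,
    n_s = n_s, s_max = s_max,
    n_sigma_s = n_sigma_s, sigma_s_max = sigma_s_max,
    min_frames = min_frames, min_displacement_um = min_displacement_um,
    angle_convention = angle_convention
  )
}

#' Track retention filters
#'
#' A track is retained when it has at least `min_frames` consecutive
#' positions and its maximal displacement from the first position is at
#' least `min_displacement_um`.
#'
#' @param xy position matrix (micrometers).
#' @param config a [cell_config()].
#' @return `TRUE`/`FALSE` with attribute `reason` on rejection.
#' @export
cell_track_ok <- function(xy, config = cell_config()) {
  xy <- as.matrix(xy)
  if (nrow(xy) < config$min_frames) {
    return(structure(FALSE, reason = "too short"))
  }
  disp <- sqrt((xy[, 1] - xy[1, 1])^2 + (xy[, 2] - xy[1, 2])^2)
  if (max(disp) < config$min_displacement_um) {
    return(structure(FALSE, reason = "insufficient displacement"))
  }
  TRUE
}

#' Cell-migration study: time-varying persistence and speed
#'
#' Runs, per retained track and independently per channel, a
#' hyper-study over the drift magnitude of a Gaussian random walk
#' (turning angles: von Mises/kappa with a flat prior; speeds:
#' Rayleigh/s with its Jeffreys prior), extracts the hyper-averaged
#' smoothed mean paths, and pools all per-step means into the
#' persistence-speed correlation. Speed steps are aligned to angle
#' steps by dropping the first speed (an angle at step t compares the
#' movements arriving at t and t+1).
#'
#' @param tracks list of tracks as returned by [read_trajectories()],
#'   or of `list(xy =, frame_min =)`.
#' @param config a [cell_config()].
#' @return List with `cells` (per-cell results: mean paths, hyper
#'   marginals), `correlation` (pooled Pearson rho), `n_retained`,
#'   `excluded` (reasons).
#' @export
cell_study <- function(tracks, config = cell_config()) {
  kgrid <- param_grid(0, config$kappa_max, config$n_kappa, names = "kappa")
  sgrid <- param_grid(0, config$s_max, config$n_s, names = "s")
  kobs <- obs_vonmises(kgrid)
  sobs <- obs_rayleigh(sgrid)
  kprior <- flat_prior(kgrid)
  sprior <- jeffreys_prior(sgrid, "rayleigh")
  sig_k <- seq(0, config$sigma_kappa_max, length.out = config$n_sigma_kappa)
  sig_s <- seq(0, config$sigma_s_max, length.out = config$n_sigma_s)

  cells <- list()
  excluded <- character(0)
  pooled_k <- numeric(0)
  pooled_s <- numeric(0)
  for (tr in tracks) {
    ok <- cell_track_ok(tr$xy, config)
    if (!isTRUE(ok)) {
      excluded <- c(excluded, attr(ok, "reason"))
      next
    }
    phi <- turning_angles(tr$xy, convention = config$angle_convention)
    v <- speeds(tr$xy, frame_min = tr$frame_min)
    if (all(is.na(phi))) {
      excluded <- c(excluded, "no defined turning angle")
      next
    }
    kst <- hyper_study(
      as.numeric(phi), kobs,
      function(eta) if (eta$sigma > 0) trans_gaussian_rw(eta$sigma)
        else trans_identity(),
      data.frame(sigma = sig_k), kprior, keep = "mean_path"
    )
    sst <- hyper_study(
      v, sobs,
      function(eta) if (eta$sigma > 0) trans_gaussian_rw(eta$sigma)
        else trans_identity(),
      data.frame(sigma = sig_s), sprior, keep = "mean_path"
    )
    kbar <- kst$mean_paths[, "kappa"]
    sbar <- sst$mean_paths[, "s"]
    # angle step t spans movements t and t+1; speed step t+1 is the
    # contemporaneous one
    sbar_al <- sbar[-1]
    cells[[length(cells) + 1L]] <- list(
      cell_id = tr$cell_id, kappa_path = kbar, s_path = sbar,
      sigma_kappa_marginal = hyper_marginal(kst, "sigma"),
      sigma_s_marginal = hyper_marginal(sst, "sigma")
    )
    keep_t <- !is.na(kbar)
    pooled_k <- c(pooled_k, kbar[keep_t])
    pooled_s <- c(pooled_s, sbar_al[keep_t])
  }
  correlation <- if (length(pooled_k) >= 3L) {
    stats::cor(pooled_k, pooled_s)
  } else NA_real_
  if (length(excluded)) {
    message(sprintf("excluded %d track(s): %s", length(excluded),
                    paste(excluded, collapse = "; ")))
  }
  list(
    cells = cells, correlation = correlation,
    n_retained = length(cells), excluded = excluded,
    pooled = data.frame(kappa = pooled_k, s = pooled_s)
  )
}
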