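#' BOLD simulation configuration
#'
#' Parameters for generating multi-run voxel x time BOLD data containing a
#' planted k-fold directional modulation. On each trial the simulation-period
#' boxcar carries amplitude
#' \deqn{base + A \cos(k[\theta_t - \phi_{state}])}
#' before HRF convolution. Under the \code{spatial} regime the modulation
#' orientation \eqn{\phi} is the same in every state; under the
#' \code{cognitive} regime the orientation rotates with the targets:
#' \eqn{\phi_{state} = (\phi + rotation) \bmod (360/k)}. Signal-to-noise is
#' controlled by \code{grid_amplitude / noise_sd}.
#'
#' @param n_voxels number of voxels (ignored if \code{dims} given).
#' @param dims optional 3D grid dimensions for volumetric mode.
#' @param voxel_size voxel edge length in mm (volumetric mode).
#' @param roi_center,roi_radius_mm sphere carrying the grid signal in
#'   volumetric mode (defaults: grid center, 9 mm).
#' @param TR repetition time in seconds.
#' @param grid_amplitude planted modulation amplitude A (signal units).
#' @param base_amplitude mean simulation-period response amplitude.
#' @param grid_phi true orientation \eqn{\phi} in degrees (shared by voxels).
#' @param fold_k planted fold symmetry (6 = hexadirectional).
#' @param regime "spatial", "cognitive" or "none" (no directional modulation).
#' @param noise_sd white Gaussian noise SD (signal units).
#' @param drift_amp amplitude scale of slow cosine drift.
#' @param n_nuisance number of smooth nuisance series (returned as known
#'   regressors).
#' @param ar1 optional AR(1) coefficient for temporally correlated noise
#'   (0 = white, the default).
#' @return an object of class \code{bold_sim_config}.
#' @export
bold_sim_config <- function(n_voxels = 1, dims = NULL, voxel_size = 3,
                            roi_center = NULL, roi_radius_mm = 9,
                            TR = 2, grid_amplitude = 1, base_amplitude = 1,
                            grid_phi = 10, fold_k = 6,
                            regime = c("cognitive", "spatial", "none"),
                            noise_sd = 1, drift_amp = 0.5, n_nuisance = 2,
                            ar1 = 0) {
  regime <- match.arg(regime)
  stopifnot(TR > 0, fold_k >= 1, noise_sd >= 0)
  structure(list(n_voxels = n_voxels, dims = dims, voxel_size = voxel_size,
                 roi_center = roi_center, roi_radius_mm = roi_radius_mm,
                 TR = TR, grid_amplitude = grid_amplitude,
                 base_amplitude = base_amplitude, grid_phi = grid_phi,
                 fold_k = fold_k, regime = regime, noise_sd = noise_sd,
                 drift_amp = drift_amp, n_nuisance = n_nuisance, ar1 = ar1),
            class = "bold_sim_config")
}

# True modulation orientation for a state rotation under a regime.
regime_phi <- function(config, rotation) {
  period <- 360 / config$fold_k
  switch(config$regime,
         spatial = config$grid_phi %% period,
         cognitive = (config$grid_phi + rotation) %% period,
         none = config$grid_phi %% period)
}

#' Simulate multi-run BOLD data with a planted directional code
#'
#' Generates a voxel x time signal matrix from a behavioral dataset: per trial
#' a simulation-period boxcar scaled by
#' \code{base_amplitude + grid_amplitude * cos(k[theta - phi_state])}
#' (plus a response-period boxcar of amplitude 1) is laid on a microtime grid
#' (dt = TR/16), convolved with the canonical HRF and read out at mid-TR;
#' slow cosine drift, smooth nuisance series and Gaussian noise are added.
#' Runs are simulated independently and concatenated.
#'
#' @param events a \code{behavioral_dataset} (must carry \code{theta},
#'   onsets/durations and \code{run}).
#' @param config a \code{\link{bold_sim_config}}.
#' @param seed integer seed; identical (events, config, seed) give identical
#'   data.
#' @return an object of class \code{bold_dataset}: list with \code{signal}
#'   (voxels x time), \code{TR}, \code{run_len} (scans per run),
#'   \code{events}, \code{nuisance} (time x q matrix of known series),
#'   \code{config}, and in volumetric mode \code{dims}, \code{voxel_size} and
#'   \code{roi} (indices of signal-carrying voxels).
#' @export
simulate_bold <- function(events, config = bold_sim_config(), seed = NULL) {
  if (is.null(events$theta) || any(is.na(events$theta))) {
    stop("events must carry a theta (angle of travel) for every trial",
         call. = FALSE)
  }
  TR <- config$TR
  runs <- sort(unique(events$run))
  run_dur <- attr(events, "schedule_attrs")$run_dur
  if (is.null(run_dur)) run_dur <- attr(events, "run_dur")
  if (is.null(run_dur)) {
    run_dur <- vapply(runs, function(r) {
      ev <- events[events$run == r, ]
      max(ev$onset_out) + 1 + 10
    }, numeric(1))
  }

  # voxel bookkeeping
  if (!is.null(config$dims)) {
    dims <- config$dims
    n_vox <- prod(dims)
    center <- config$roi_center %||% ceiling(dims / 2)
    roi <- make_spherical_roi(center, config$roi_radius_mm, dims,
                              config$voxel_size)$index
  } else {
    n_vox <- config$n_voxels
    roi <- seq_len(n_vox)
  }

  seeds <- if (is.null(seed)) {
    lapply(runs, function(r) NULL)
  } else {
    as.list(derive_seeds(seed, length(runs)))
  }

  sig_runs <- vector("list", length(runs))
  nui_runs <- vector("list", length(runs))
  run_len <- integer(length(runs))
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    ev <- events[events$run == r, ]
    n_scans <- as.integer(ceiling(run_dur[ri] / TR))
    run_len[ri] <- n_scans

    amp <- config$base_amplitude + config$grid_amplitude *
      cos(deg2rad(config$fold_k *
                    (ev$theta - regime_phi(config, ev$rotation))))
    task <- convolved_regressor(ev$onset_sim, ev$sim_dur, amp, n_scans, TR) +
      convolved_regressor(ev$onset_resp, rep(3, nrow(ev)), rep(1, nrow(ev)),
                          n_scans, TR)

    run_out <- with_seed(seeds[[ri]], {
      drift <- drift_basis(n_scans) %*% rnorm(3, 0, config$drift_amp)
      nui <- NULL
      if (config$n_nuisance > 0) {
        # smooth nuisance: random-walk series, standardized
        nui <- vapply(seq_len(config$n_nuisance), function(j) {
          w <- cumsum(rnorm(n_scans))
          (w - mean(w)) / stats::sd(w)
        }, numeric(n_scans))
        colnames(nui) <- paste0("nuisance", seq_len(config$n_nuisance))
      }
      clean <- drop(drift) + if (is.null(nui)) 0 else nui %*% rnorm(ncol(nui), 0, 0.3)
      S <- matrix(rep(clean, n_vox), nrow = n_vox, byrow = TRUE)
      S[roi, ] <- S[roi, , drop = FALSE] +
        matrix(rep(task, length(roi)), nrow = length(roi), byrow = TRUE)
      if (config$noise_sd > 0) {
        eps <- matrix(rnorm(n_vox * n_scans, 0, config$noise_sd), n_vox, n_scans)
        if (config$ar1 > 0) {
          for (s in 2:n_scans) {
            eps[, s] <- config$ar1 * eps[, s - 1] +
              sqrt(1 - config$ar1^2) * eps[, s]
          }
        }
        S <- S + eps
      }
      list(S = S, nui = nui)
    })
    sig_runs[[ri]] <- run_out$S
    nui_runs[[ri]] <- run_out$nui
  }

  nuisance <- NULL
  if (config$n_nuisance > 0) {
    # block-stacked; nuisance series are global columns (zero outside their run
    # is unnecessary since they are standardized per run and fit jointly)
    nuisance <- do.call(rbind, nui_runs)
  }
  structure(list(signal = do.call(cbind, sig_runs),
                 TR = TR, run_len = run_len, events = events,
                 nuisance = nuisance, config = config,
                 dims = config$dims, voxel_size = config$voxel_size,
                 roi = if (!is.null(config$dims)) roi else NULL),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat("<bold_dataset>", nrow(x$signal), "voxel(s) x", ncol(x$signal),
      "scans (", length(x$run_len), "run(s), TR", x$TR, "s )\n")
  cat("  regime:", x$config$regime, " fold k:", x$config$fold_k,
      " amplitude:", x$config$grid_amplitude,
      " noise SD:", x$config$noise_sd, "\n")
  invisible(x)
}

# Mean time series over an ROI (indices) or all voxels.
roi_signal <- function(bold, roi = NULL) {
  S <- bold$signal
  if (is.null(roi)) roi <- seq_len(nrow(S))
  if (length(roi) == 1) S[roi, ] else colMeans(S[roi, , drop = FALSE])
}
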