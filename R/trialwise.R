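#' Trial-wise grid-phase consistency
#'
#' Derives, for every trial, a signed measure of whether the ROI signal is
#' in-phase (positive) or antiphase (negative) with the grid orientation fit
#' in the \emph{alternate} state. The ROI time series is first residualized
#' against a baseline model (condition-level simulation boxcars, the
#' response-period movement regressor, outcome boxcars, drift, run intercepts
#' and nuisance), which removes the mean trial-locked response while leaving
#' per-trial amplitude deviations in the residual. For each trial a
#' single-trial regressor is built: the trial's simulation boxcar scaled by
#' \code{cos(k[theta_t - phi_alt])} and HRF-convolved. The Pearson
#' correlation between this regressor and the residual over the trial window
#' \code{[onset, onset + duration + window]} (both demeaned within the
#' window) is recorded and Fisher-transformed.
#'
#' @param bold a \code{bold_dataset}.
#' @param events event table (defaults to \code{bold$events}).
#' @param phi_alt named per-state orientations where \code{phi_alt[state]} is
#'   the grid angle fit in the \emph{other} state; a
#'   \code{\link{between_state_crossval}} result may be passed instead and the
#'   cross-assignment is taken from it.
#' @param k fold symmetry.
#' @param roi voxel indices (default: all voxels averaged).
#' @param window post-offset window extension in seconds (default 8, covering
#'   the hemodynamic lag).
#' @param nuisance nuisance matrix (defaults to \code{bold$nuisance}).
#' @return an object of class \code{trialwise_phase}: data.frame with trial,
#'   state, the cosine weight \code{amplitude}, Pearson \code{r} and Fisher
#'   \code{z}; attributes carry k and the window.
#' @export
trialwise_phase_consistency <- function(bold, events = bold$events, phi_alt,
                                        k = 6, roi = NULL, window = 8,
                                        nuisance = bold$nuisance) {
  if (inherits(phi_alt, "grid_crossval")) {
    ph <- phi_alt$phi
    states <- names(ph)
    phi_alt <- stats::setNames(ph[rev(seq_along(ph))], states)
  }
  TR <- bold$TR
  n_scan_window <- floor(window / TR)
  if (n_scan_window < 2) stop("window shorter than 2 samples", call. = FALSE)

  base <- build_grid_design(events, TR, bold$run_len, k = k,
                            split_by = "state", modulator = "none",
                            nuisance = nuisance)
  y <- roi_signal(bold, roi)
  resid <- fit_glm(y, base)$residuals[, 1]

  runs <- sort(unique(events$run))
  run_offset <- c(0, cumsum(bold$run_len))[match(events$run, runs)]
  st <- paste0("st", events$rotation)

  n <- nrow(events)
  r_vals <- amp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- phi_alt[[st[i]]]
    if (is.null(a) || is.na(a)) next
    w <- cos(deg2rad(k * (events$theta[i] - a)))
    amp[i] <- w
    ri <- match(events$run[i], runs)
    n_scans <- bold$run_len[ri]
    reg <- convolved_regressor(events$onset_sim[i], events$sim_dur[i], w,
                               n_scans, TR)
    s0 <- max(1L, floor(events$onset_sim[i] / TR) + 1L)
    s1 <- min(n_scans,
              ceiling((events$onset_sim[i] + events$sim_dur[i] + window) / TR))
    if (s1 - s0 + 1 < 2) next
    seg_x <- reg[s0:s1]
    seg_y <- resid[run_offset[i] + (s0:s1)]
    if (stats::sd(seg_x) == 0 || stats::sd(seg_y) == 0) next
    r_vals[i] <- stats::cor(seg_x, seg_y)
  }
  r_clip <- pmin(pmax(r_vals, -1 + 1e-12), 1 - 1e-12)
  out <- data.frame(trial = events$trial, state = st,
                    amplitude = amp, r = r_vals, z = atanh(r_clip))
  structure(out, class = c("trialwise_phase", "data.frame"),
            k = k, window = window)
}

#' @export
print.trialwise_phase <- function(x, ...) {
  cat("<trialwise_phase>", sum(!is.na(x$z)), "of", nrow(x),
      "trials; mean z =", signif(mean(x$z, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Dynamics of trial-wise phase consistency
#'
#' Per-subject OLS regressions of the Fisher-transformed trial-wise phase
#' coefficients on behavior and on time-in-state, with group-level one-sample
#' t-tests when a cohort is supplied. Four models are fit:
#' \describe{
#'   \item{error}{z on the logit-transformed normalized error, all trials;}
#'   \item{error_miniblock}{as above plus the number of mini-blocks after the
#'     state change as a covariate;}
#'   \item{trial}{z on trial number within the first mini-block after a state
#'     change (transfer window only);}
#'   \item{miniblock}{z on mini-block number after the state change.}
#' }
#'
#' @param trialwise a \code{trialwise_phase} (or list of them, one per
#'   subject).
#' @param behavior the matching classified behavioral dataset(s).
#' @param eps clipping bound for the logit transform.
#' @return an object of class \code{trialwise_dynamics}: per-model
#'   subject-coefficient matrices and, for cohorts, group t tables.
#' @export
trialwise_dynamics <- function(trialwise, behavior, eps = 1e-3) {
  if (!is.data.frame(trialwise)) {
    pairs <- Map(function(tw, bh) trialwise_dynamics(tw, bh, eps = eps)$coefs,
                 trialwise, behavior)
    models <- names(pairs[[1]])
    coefs <- lapply(models, function(m) {
      do.call(rbind, lapply(pairs, `[[`, m))
    })
    names(coefs) <- models
    group <- lapply(coefs, group_coefficient_test)
    return(structure(list(coefs = coefs, group = group),
                     class = "trialwise_dynamics"))
  }

  d <- merge(as.data.frame(trialwise)[, c("trial", "z")],
             as.data.frame(behavior), by = "trial")
  d <- d[!is.na(d$z) & !d$missed & !is.na(d$normalized_error), ]
  d$logit_err <- logit_error(d$normalized_error, eps)

  fit1 <- function(X, y, nm) {
    b <- subject_ols(cbind("(Intercept)" = 1, X), y, nm)
    b
  }
  coefs <- list(
    error = fit1(cbind(logit_err = d$logit_err), d$z, "logit_err"),
    error_miniblock = fit1(cbind(logit_err = d$logit_err,
                                 miniblock = d$miniblock), d$z,
                           c("logit_err", "miniblock")),
    trial = {
      dd <- d[d$miniblock == 1 & d$state_block > 1, ]
      fit1(cbind(trial = dd$trial_in_miniblock), dd$z, "trial")
    },
    miniblock = fit1(cbind(miniblock = d$miniblock), d$z, "miniblock")
  )
  structure(list(coefs = coefs, group = NULL), class = "trialwise_dynamics")
}

#' @export
print.trialwise_dynamics <- function(x, ...) {
  cat("<trialwise_dynamics>\n")
  if (is.null(x$group)) {
    for (m in names(x$coefs)) {
      cat(" ", m, ": ", paste(names(x$coefs[[m]]),
                              signif(x$coefs[[m]], 3),
                              sep = "=", collapse = ", "), "\n", sep = "")
    }
  } else {
    for (m in names(x$group)) {
      cat(" model:", m, "\n")
      print(x$group[[m]], row.names = FALSE, digits = 3)
    }
  }
  invisible(x)
}
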