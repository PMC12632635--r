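#' Single-trial t-statistic patterns
#'
#' Estimates one GLM per trial in the style of least-squares-single beta
#' series: the model contains a single regressor for the simulation period of
#' the trial of interest, one regressor pooling all other simulation periods,
#' regressors for all outcomes and all responses, drift, run intercepts and
#' nuisance. The trial regressor's t-statistic map is stored. Missed trials
#' are excluded from the pattern set (no meaningful response).
#'
#' @param bold a \code{bold_dataset}.
#' @param events event table (defaults to \code{bold$events}).
#' @param nuisance nuisance matrix (defaults to \code{bold$nuisance}).
#' @param include logical vector of trials to keep (default: non-missed).
#' @return an object of class \code{trial_patterns}: \code{t} (trial x voxel
#'   t-statistic matrix), \code{trials} (their trial ids), \code{events}.
#' @export
single_trial_maps <- function(bold, events = bold$events,
                              nuisance = bold$nuisance,
                              include = NULL) {
  if (is.null(include)) {
    include <- if (!is.null(events$missed)) !events$missed else
      rep(TRUE, nrow(events))
  }
  idx <- which(include)
  if (length(idx) < 2) stop("need >= 2 included trials", call. = FALSE)
  TR <- bold$TR
  runs <- sort(unique(events$run))
  n_runs <- length(runs)
  run_len <- bold$run_len
  total <- sum(run_len)
  run_rows <- split(seq_len(total), rep(seq_len(n_runs), run_len))
  Y <- t(bold$signal)
  if (nrow(Y) != total) stop("signal/run length mismatch", call. = FALSE)

  # shared columns: all-outcomes, all-responses, drift+intercept, nuisance
  shared <- matrix(0, total, 2, dimnames = list(NULL, c("outcome", "response")))
  all_sim <- numeric(total)
  for (ri in seq_len(n_runs)) {
    ev <- events[events$run == runs[ri], ]
    rows <- run_rows[[ri]]
    n_scans <- run_len[ri]
    shared[rows, "outcome"] <- convolved_regressor(ev$onset_out,
                                                   rep(1, nrow(ev)),
                                                   rep(1, nrow(ev)), n_scans, TR)
    shared[rows, "response"] <- convolved_regressor(ev$onset_resp,
                                                    rep(3, nrow(ev)),
                                                    rep(1, nrow(ev)), n_scans, TR)
    all_sim[rows] <- convolved_regressor(ev$onset_sim, ev$sim_dur,
                                         rep(1, nrow(ev)), n_scans, TR)
  }
  n_drift <- 3
  X_drift <- matrix(0, total, n_runs * (n_drift + 1))
  for (ri in seq_len(n_runs)) {
    cols <- (ri - 1) * (n_drift + 1) + seq_len(n_drift + 1)
    X_drift[run_rows[[ri]], cols] <- cbind(drift_basis(run_len[ri]), 1)
  }
  X_nui <- NULL
  if (!is.null(nuisance)) X_nui <- as.matrix(nuisance)

  tmaps <- matrix(NA_real_, length(idx), ncol(Y))
  for (m in seq_along(idx)) {
    i <- idx[m]
    ri <- match(events$run[i], runs)
    target <- numeric(total)
    target[run_rows[[ri]]] <- convolved_regressor(events$onset_sim[i],
                                                  events$sim_dur[i], 1,
                                                  run_len[ri], TR)
    others <- all_sim - target
    X <- cbind(target = target, others = others, shared, X_drift, X_nui)
    if (ncol(X) >= nrow(X)) {
      stop("fewer time points than design columns", call. = FALSE)
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      stop("rank-deficient single-trial design at trial ", events$trial[i],
           " (duplicate trial timing?)", call. = FALSE)
    }
    beta <- qr.coef(qrX, Y)
    res <- Y - X %*% beta
    df <- nrow(X) - ncol(X)
    sigma2 <- colSums(res^2) / df
    A <- chol2inv(qr.R(qrX)); ip <- order(qrX$pivot)
    v11 <- A[ip, ip][1, 1]
    tmaps[m, ] <- beta[1, ] / sqrt(v11 * sigma2)
  }
  structure(list(t = tmaps, trials = events$trial[idx],
                 events = events[idx, , drop = FALSE]),
            class = "trial_patterns")
}

#' @export
print.trial_patterns <- function(x, ...) {
  cat("<trial_patterns>", nrow(x$t), "trials x", ncol(x$t), "voxels\n")
  invisible(x)
}

#' Neural representational dissimilarity matrix
#'
#' 1 - Pearson correlation between trial patterns; entries in [0, 2], zero
#' diagonal by construction.
#'
#' @param patterns a \code{trial_patterns} or a trial x voxel matrix.
#' @param voxels optional voxel subset.
#' @return a symmetric trial x trial dissimilarity matrix.
#' @export
neural_rdm <- function(patterns, voxels = NULL) {
  M <- if (inherits(patterns, "trial_patterns")) patterns$t else as.matrix(patterns)
  if (!is.null(voxels)) M <- M[, voxels, drop = FALSE]
  D <- 1 - stats::cor(t(M))
  diag(D) <- 0
  D
}

# indicator RDM: 0 where both trials share the category, 1 otherwise
indicator_rdm <- function(f) outer(f, f, `!=`) * 1

#' Hypothesis and covariate RDMs for the task
#'
#' Builds the model dissimilarity matrices regressed against the neural RDM.
#' RDMs of interest: \code{position} (Euclidean distance between the
#' current-state mean target positions of the two trials' colors),
#' \code{position_invariant} (distances between the original-configuration
#' target positions, identical across states), \code{identity} (same shield
#' color similar, uniformly dissimilar otherwise) and \code{transfer_trials}
#' (first post-change mini-block trials similar to each other). Covariates:
#' run, state-block, state, within-state identity, absolute difference in the
#' response-angle change since the last same-color presentation, CIELAB
#' (CIE76) color distance, movement distance, start-/end-position distances
#' and within-run lag indicators for lags 1..16.
#'
#' @param events classified event table of the included trials (aligned with
#'   the pattern set).
#' @param config a \code{\link{task_config}} (for CIELAB coordinates).
#' @param lags lag indicator depths (default 1:16).
#' @param which optional character vector restricting the returned set.
#' @return named list of trial x trial matrices, each with a \code{kind}
#'   attribute ("hypothesis" or "covariate").
#' @export
build_hypothesis_rdms <- function(events, config = attr(events, "config"),
                                  lags = 1:16, which = NULL) {
  ev <- as.data.frame(events)
  n <- nrow(ev)
  out <- list()
  add <- function(name, m, kind) {
    diag(m) <- 0
    out[[name]] <<- structure(m, kind = kind)
  }

  # mean target position of each trial's color in the current state
  pd <- function(x, y) {
    as.matrix(stats::dist(cbind(x, y)))
  }
  add("position", pd(ev$target_curr_x, ev$target_curr_y), "hypothesis")
  # state-invariant: original-configuration position of the color
  ang <- -ev$rotation
  ox <- ev$target_curr_x * cos(deg2rad(ang)) - ev$target_curr_y * sin(deg2rad(ang))
  oy <- ev$target_curr_x * sin(deg2rad(ang)) + ev$target_curr_y * cos(deg2rad(ang))
  add("position_invariant", pd(ox, oy), "hypothesis")
  add("identity", indicator_rdm(ev$color), "hypothesis")
  add("transfer_trials",
      indicator_rdm(ev$miniblock == 1 & ev$state_block > 1), "hypothesis")

  add("run", indicator_rdm(ev$run), "covariate")
  add("state_block", indicator_rdm(ev$state_block), "covariate")
  add("state", indicator_rdm(ev$rotation), "covariate")
  add("identity_within_state",
      indicator_rdm(paste(ev$color, ev$rotation)), "covariate")

  # response-angle change since the previous same-color presentation
  resp_ang <- point_angle(ev$resp_x, ev$resp_y)
  delta <- rep(0, n)
  for (cl in unique(ev$color)) {
    ix <- which(ev$color == cl)
    if (length(ix) > 1) {
      delta[ix[-1]] <- angular_distance(resp_ang[ix[-1]], resp_ang[ix[-length(ix)]])
    }
  }
  add("response_change", abs(outer(delta, delta, `-`)), "covariate")

  if (is.null(config)) {
    lab <- color_lab_palette(max(ev$color))
  } else {
    lab <- config$color_lab
    if (max(ev$color) > nrow(lab)) lab <- color_lab_palette(max(ev$color))
  }
  if (anyNA(lab[unique(ev$color), ])) {
    stop("missing CIELAB triplet for one or more colors", call. = FALSE)
  }
  de <- as.matrix(stats::dist(lab))            # CIE76 delta-E
  add("color_lab", de[ev$color, ev$color], "covariate")

  add("movement", abs(outer(ev$movement, ev$movement, `-`)), "covariate")
  add("start_position", pd(ev$start_x, ev$start_y), "covariate")
  add("end_position", pd(ev$resp_x, ev$resp_y), "covariate")

  same_run <- outer(ev$run, ev$run, `==`)
  trial_gap <- abs(outer(seq_len(n), seq_len(n), `-`))
  for (d in lags) {
    m <- (trial_gap == d & same_run) * 1
    if (any(m[lower.tri(m)] != 0)) add(paste0("lag", d), m, "covariate")
  }

  if (!is.null(which)) out <- out[intersect(which, names(out))]
  out
}

#' Regress hypothesis RDMs on a neural RDM
#'
#' Vectorizes the strict lower triangle of the neural RDM and of each model
#' RDM, z-scores every vector, and fits OLS with an intercept. The z-scoring
#' makes coefficients invariant to affine rescaling of individual model RDMs.
#'
#' @param neural trial x trial neural dissimilarity matrix.
#' @param hypothesis_set named list of model RDMs
#'   (\code{\link{build_hypothesis_rdms}}).
#' @param cor_limit absolute pairwise predictor correlation above which the
#'   pair is reported as collinear (default 0.99).
#' @return named numeric vector of coefficients (one per model RDM).
#' @export
rdm_regression <- function(neural, hypothesis_set, cor_limit = 0.99) {
  lt <- lower.tri(neural)
  y <- zscore(neural[lt], "neural RDM")
  P <- vapply(names(hypothesis_set),
              function(nm) zscore(hypothesis_set[[nm]][lt], nm),
              numeric(sum(lt)))
  if (ncol(P) > 1) {
    cm <- abs(stats::cor(P)); diag(cm) <- 0
    if (any(cm > cor_limit)) {
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      stop("collinear hypothesis RDMs: ", colnames(P)[ij[1]], " ~ ",
           colnames(P)[ij[2]], " (|r| = ", round(max(cm), 4), ")",
           call. = FALSE)
    }
  }
  X <- cbind("(Intercept)" = 1, P)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient RDM regression; column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(qr.coef(qrX, y)[-1], names(hypothesis_set))
}
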