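#' Between-state cross-validation of the grid orientation
#'
#' Tests whether a region's k-fold directional code is anchored to the fixed
#' screen space (a spatial code) or rotates with the target configuration (a
#' cognitive code). The grid orientation phi is first fit independently in
#' each of the two rotation states from the quadrature GLM. A second GLM then
#' replaces each state's quadrature pair with a single predicted modulator
#' built from the \emph{other} state's orientation,
#' \code{cos(k[theta_t - phi_other])}, so the modulator for state-Y trials
#' reflects the prediction from state X and vice versa. Under a 90-degree
#' rotation and k = 6 the two true orientations are in-phase for a spatial
#' code (positive cross-predicted coefficients) and precisely antiphase -
#' 30 degrees apart - for a cognitive code (negative coefficients).
#'
#' @param bold a \code{bold_dataset}.
#' @param events event table (defaults to \code{bold$events}).
#' @param k fold symmetry.
#' @param roi voxel indices (default: all voxels averaged).
#' @param simultaneous fit both cross-predicted modulators in one GLM
#'   (default); \code{FALSE} fits one GLM per direction with the other
#'   state's boxcar unmodulated.
#' @param nuisance nuisance matrix (defaults to \code{bold$nuisance}).
#' @return an object of class \code{grid_crossval}: \code{coefficients}
#'   (named per state: the coefficient of that state's cross-predicted
#'   modulator), \code{mean} (their arithmetic mean), \code{phi} (the
#'   per-state orientations used), \code{k}, \code{mode = "between"}.
#' @export
between_state_crossval <- function(bold, events = bold$events, k = 6,
                                   roi = NULL, simultaneous = TRUE,
                                   nuisance = bold$nuisance) {
  states <- sort(unique(paste0("st", events$rotation)))
  if (length(states) < 2) {
    stop("between-state cross-validation needs >= 2 states", call. = FALSE)
  }
  if (length(states) > 2) {
    stop("between-state cross-validation is defined for exactly 2 states; got ",
         length(states), call. = FALSE)
  }
  gf <- grid_glm(bold, events, k = k, split_by = "state", roi = roi,
                 nuisance = nuisance)
  phi <- stats::setNames(gf$angles$phi, gf$angles$state)
  if (anyNA(phi[states])) {
    stop("could not fit a grid angle in every state", call. = FALSE)
  }
  # cross assignment: each state's trials get the other state's angle
  phi_cross <- stats::setNames(phi[rev(states)], states)
  y <- roi_signal(bold, roi)

  if (simultaneous) {
    design <- build_grid_design(events, bold$TR, bold$run_len, k = k,
                                split_by = "state", modulator = "predicted",
                                phi = phi_cross, nuisance = nuisance)
    fit <- fit_glm(y, design)
    cols <- paste0("correct_", states, "_pred", k)
    coefs <- stats::setNames(fit$coef[cols, 1], states)
  } else {
    coefs <- vapply(states, function(st) {
      # one GLM per direction: only this state's modulator kept
      design <- build_grid_design(events, bold$TR, bold$run_len, k = k,
                                  split_by = "state", modulator = "predicted",
                                  phi = phi_cross, nuisance = nuisance)
      X <- design$X
      drop_col <- setdiff(grep(paste0("_pred", k, "$"), colnames(X),
                               value = TRUE),
                          paste0("correct_", st, "_pred", k))
      design$X <- X[, setdiff(colnames(X), drop_col), drop = FALSE]
      fit <- fit_glm(y, design)
      fit$coef[paste0("correct_", st, "_pred", k), 1]
    }, numeric(1))
  }
  structure(list(coefficients = coefs, mean = mean(coefs),
                 phi = phi[states], k = k, mode = "between",
                 grid_fit = gf),
            class = "grid_crossval")
}

#' Within-state leave-one-run-out cross-validation
#'
#' Reliability test of the grid orientation inside each state: quadrature
#' pairs are fit per state and run; for each held-out run the circular mean
#' orientation over the remaining runs (averaged in k-angle space) generates
#' the predicted modulator \code{cos(k[theta - mean phi])} for the same state
#' in the held-out run. Coefficients are averaged over held-out runs and
#' states. A stable orientation across runs yields positive coefficients.
#'
#' @inheritParams between_state_crossval
#' @return a \code{grid_crossval} with \code{mode = "within"};
#'   \code{coefficients} is named \code{<state>_r<heldout run>}.
#' @export
within_state_crossval <- function(bold, events = bold$events, k = 6,
                                  roi = NULL, nuisance = bold$nuisance) {
  runs <- sort(unique(events$run))
  if (length(runs) < 2) {
    stop("within-state cross-validation needs >= 2 runs", call. = FALSE)
  }
  gf <- grid_glm(bold, events, k = k, split_by = "state_run", roi = roi,
                 nuisance = nuisance)
  ang <- gf$angles
  states <- sort(unique(ang$state))
  y <- roi_signal(bold, roi)

  coefs <- c()
  for (r in runs) {
    # LOO mean orientation per state (circular mean in k-angle space)
    phi_bar <- vapply(states, function(st) {
      rest <- ang$phi[ang$state == st & ang$run != r]
      if (length(rest) == 0) return(NA_real_)
      circular_mean_angle(rest, k)
    }, numeric(1))
    if (anyNA(phi_bar)) next
    # fit the predicted modulators on the held-out run only
    ev_r <- events[events$run == r, ]
    attr(ev_r, "run_dur") <- sum(bold$run_len[match(r, runs)]) * bold$TR
    ri <- match(r, runs)
    rows <- split(seq_len(sum(bold$run_len)),
                  rep(seq_along(bold$run_len), bold$run_len))[[ri]]
    ev_r$run <- 1L
    nui_r <- if (is.null(nuisance)) NULL else nuisance[rows, , drop = FALSE]
    design <- build_grid_design(ev_r, bold$TR, bold$run_len[ri], k = k,
                                split_by = "state", modulator = "predicted",
                                phi = phi_bar, nuisance = nui_r)
    fit <- fit_glm(y[rows], design)
    for (st in states) {
      cn <- paste0("correct_", st, "_pred", k)
      if (cn %in% rownames(fit$coef)) {
        coefs[paste0(st, "_r", r)] <- fit$coef[cn, 1]
      }
    }
  }
  structure(list(coefficients = coefs, mean = mean(coefs),
                 phi = stats::setNames(ang$phi, paste0(ang$state, "_r", ang$run)),
                 k = k, mode = "within", grid_fit = gf),
            class = "grid_crossval")
}

#' @export
print.grid_crossval <- function(x, ...) {
  cat("<grid_crossval>", x$mode, "-state test, k =", x$k, "\n")
  print(round(x$coefficients, 4))
  cat("  mean coefficient:", signif(x$mean, 4))
  if (x$mode == "between") {
    cat("  (positive: spatial / in-phase; negative: cognitive / antiphase)")
  }
  cat("\n")
  invisible(x)
}

#' Fold-symmetry specificity scan
#'
#' Repeats a cross-validation test for several candidate fold symmetries
#' (default 4, 5, 6, 7, 8, i.e. 90, 72, 60, 51.4 and 45 degree
#' periodicities). A genuine hexadirectional code should produce an effect
#' only at k = 6.
#'
#' @param bold a \code{bold_dataset}.
#' @param events event table.
#' @param folds fold symmetries to test.
#' @param mode "between" or "within".
#' @param ... passed to the cross-validation function.
#' @return an object of class \code{fold_scan}: data.frame \code{summary}
#'   (fold, periodicity, mean coefficient) and the full \code{results} list.
#' @export
fold_symmetry_scan <- function(bold, events = bold$events,
                               folds = c(4, 5, 6, 7, 8),
                               mode = c("between", "within"), ...) {
  mode <- match.arg(mode)
  fun <- if (mode == "between") between_state_crossval else within_state_crossval
  results <- lapply(folds, function(k) fun(bold, events, k = k, ...))
  names(results) <- paste0("k", folds)
  structure(list(
    summary = data.frame(fold = folds, periodicity = 360 / folds,
                         mean_coefficient = vapply(results, `[[`, numeric(1), "mean")),
    results = results, mode = mode),
    class = "fold_scan")
}

#' @export
print.fold_scan <- function(x, ...) {
  cat("<fold_scan>", x$mode, "-state cross-validation across fold symmetries\n")
  print(transform(x$summary, periodicity = round(periodicity, 1),
                  mean_coefficient = signif(mean_coefficient, 4)),
        row.names = FALSE)
  invisible(x)
}
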