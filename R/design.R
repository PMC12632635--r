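#' Build a quadrature / predicted-modulator GLM design
#'
#' Constructs the concatenated-run design matrix used throughout the grid-code
#' analyses. For every condition cell (correct / incorrect / missed responses,
#' optionally split by state or by state and run) a simulation-period boxcar
#' with the trial's simulation duration is included; modulated cells
#' additionally carry parametric modulators:
#' \describe{
#'   \item{quadrature}{\code{sin(k theta)} and \code{cos(k theta)} of the
#'     angle of travel, the regressor pair whose betas identify the grid
#'     orientation;}
#'   \item{predicted}{a single \code{cos(k[theta - phi_state])} regressor built
#'     from a supplied per-state orientation (used by the cross-validation
#'     tests);}
#'   \item{none}{no modulators (baseline model / residualizer).}
#' }
#' Modulator values are mean-centered within their condition cell before being
#' laid on the boxcar and HRF-convolved (standard parametric-modulation
#' practice; prevents collinearity with the cell's boxcar). Response-period
#' (3 s) and outcome-period (1 s) boxcars, per-run cosine drift (0.5, 1 and 2
#' cycles per run), per-run intercepts and optional unconvolved nuisance
#' columns complete the model; drift, intercept and nuisance blocks are
#' block-diagonal across runs.
#'
#' @param events a classified \code{behavioral_dataset}.
#' @param TR repetition time (seconds).
#' @param run_len integer vector of scans per run.
#' @param k fold symmetry of the modulators.
#' @param split_by "state" (default), "state_run" or "none".
#' @param modulator "quadrature", "predicted" or "none".
#' @param phi named vector of orientations (degrees) keyed by state label
#'   (\code{"st<rotation>"}); required for \code{modulator = "predicted"}.
#' @param modulate which conditions receive modulators (default correct and
#'   incorrect; missed trials are never modulated).
#' @param nuisance optional time x q matrix of nuisance series (blockified by
#'   run).
#' @param drift_freqs cosine drift frequencies in cycles per run.
#' @param oversample microtime oversampling factor (dt = TR/oversample).
#' @return an object of class \code{grid_design}: list with \code{X} (time x
#'   p named matrix), \code{groups} (column names by role), \code{run_rows},
#'   \code{cells} (per-cell trial counts), and an \code{unidentifiable}
#'   attribute listing modulated cells with no angular variance.
#' @export
build_grid_design <- function(events, TR, run_len, k = 6,
                              split_by = c("state", "state_run", "none"),
                              modulator = c("quadrature", "predicted", "none"),
                              phi = NULL,
                              modulate = c("correct", "incorrect"),
                              nuisance = NULL,
                              drift_freqs = c(0.5, 1, 2),
                              oversample = 16) {
  split_by <- match.arg(split_by)
  modulator <- match.arg(modulator)
  ev <- as.data.frame(events)
  n_runs <- length(run_len)
  runs <- sort(unique(ev$run))
  stopifnot(length(runs) == n_runs)

  cond <- as.character(trial_condition(ev))
  state <- paste0("st", ev$rotation)
  cell <- switch(split_by,
                 state = paste(cond, state, sep = "_"),
                 state_run = paste(cond, state, paste0("r", ev$run), sep = "_"),
                 none = cond)
  mod_cell <- cond %in% modulate & modulator != "none"
  if (any(mod_cell & is.na(ev$theta))) {
    stop("events missing theta for a modulated condition", call. = FALSE)
  }
  if (modulator == "predicted") {
    if (is.null(phi) || is.null(names(phi))) {
      stop("predicted modulators require a named phi vector (by state label)",
           call. = FALSE)
    }
    missing_state <- setdiff(unique(state[mod_cell]), names(phi))
    if (length(missing_state)) {
      stop("phi missing for state(s): ", paste(missing_state, collapse = ", "),
           call. = FALSE)
    }
  }

  cells <- unique(cell)
  unidentifiable <- character(0)

  # per-cell modulator values (centered within cell)
  mod_values <- list()
  for (cl in cells) {
    idx <- which(cell == cl)
    if (!any(mod_cell[idx])) next
    th <- ev$theta[idx]
    if (modulator == "quadrature") {
      s <- sin(deg2rad(k * th)); c_ <- cos(deg2rad(k * th))
      # a centered sin/cos pair needs >= 3 trials to be linearly independent
      if (length(th) < 3 ||
          (stats::sd(s) < 1e-10 && stats::sd(c_) < 1e-10)) {
        unidentifiable <- c(unidentifiable, cl)
        next
      }
      mod_values[[cl]] <- list(
        stats::setNames(list(s - mean(s), c_ - mean(c_)),
                        paste0(cl, c(paste0("_sin", k), paste0("_cos", k)))))
    } else {
      st <- state[idx][1]
      v <- cos(deg2rad(k * (th - phi[[st]])))
      if (length(th) < 2 || stats::sd(v) < 1e-10) {
        unidentifiable <- c(unidentifiable, cl)
        next
      }
      mod_values[[cl]] <- list(
        stats::setNames(list(v - mean(v)), paste0(cl, "_pred", k)))
    }
  }

  task_names <- c(paste0("sim_", cells),
                  unlist(lapply(mod_values, function(m) names(m[[1]]))),
                  "response", "outcome")
  task_names <- unique(task_names)

  blocks <- vector("list", n_runs)
  for (ri in seq_len(n_runs)) {
    r <- runs[ri]
    in_run <- ev$run == r
    n_scans <- run_len[ri]
    Xr <- matrix(0, n_scans, length(task_names),
                 dimnames = list(NULL, task_names))
    for (cl in cells) {
      sel <- in_run & cell == cl
      if (!any(sel)) next
      Xr[, paste0("sim_", cl)] <-
        convolved_regressor(ev$onset_sim[sel], ev$sim_dur[sel],
                            rep(1, sum(sel)), n_scans, TR, oversample)
      if (!is.null(mod_values[[cl]])) {
        vals <- mod_values[[cl]][[1]]
        sub <- which(cell == cl)          # cell trial order
        take <- in_run[sub]
        for (nm in names(vals)) {
          Xr[, nm] <- convolved_regressor(ev$onset_sim[sel], ev$sim_dur[sel],
                                          vals[[nm]][take], n_scans, TR,
                                          oversample)
        }
      }
    }
    Xr[, "response"] <- convolved_regressor(ev$onset_resp[in_run],
                                            rep(3, sum(in_run)),
                                            rep(1, sum(in_run)),
                                            n_scans, TR, oversample)
    Xr[, "outcome"] <- convolved_regressor(ev$onset_out[in_run],
                                           rep(1, sum(in_run)),
                                           rep(1, sum(in_run)),
                                           n_scans, TR, oversample)
    blocks[[ri]] <- Xr
  }
  X_task <- do.call(rbind, blocks)

  # block-diagonal drift + intercepts (+ nuisance)
  total <- sum(run_len)
  run_rows <- split(seq_len(total), rep(seq_len(n_runs), run_len))
  n_drift <- length(drift_freqs)
  X_drift <- matrix(0, total, n_runs * (n_drift + 1))
  dn <- character(0)
  for (ri in seq_len(n_runs)) {
    cols <- (ri - 1) * (n_drift + 1) + seq_len(n_drift + 1)
    X_drift[run_rows[[ri]], cols] <-
      cbind(drift_basis(run_len[ri], drift_freqs), 1)
    dn <- c(dn, paste0("run", ri, "_", c(paste0("drift", drift_freqs),
                                         "intercept")))
  }
  colnames(X_drift) <- dn

  X_nui <- NULL
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == total)
    q <- ncol(nuisance)
    X_nui <- matrix(0, total, n_runs * q)
    nn <- character(0)
    base_names <- colnames(nuisance) %||% paste0("nuisance", seq_len(q))
    for (ri in seq_len(n_runs)) {
      cols <- (ri - 1) * q + seq_len(q)
      X_nui[run_rows[[ri]], cols] <- nuisance[run_rows[[ri]], , drop = FALSE]
      nn <- c(nn, paste0("run", ri, "_", base_names))
    }
    colnames(X_nui) <- nn
  }

  X <- cbind(X_task, X_drift, X_nui)
  # drop all-zero columns (conditions absent in a dataset)
  keep <- colSums(abs(X)) > 0
  X <- X[, keep, drop = FALSE]

  mods <- grep(paste0("_(sin|cos|pred)", k, "$"), colnames(X), value = TRUE)
  groups <- list(
    condition = intersect(paste0("sim_", cells), colnames(X)),
    modulators = mods,
    response = "response", outcome = "outcome",
    drift = intersect(dn, colnames(X)),
    nuisance = if (is.null(X_nui)) character(0) else
      intersect(colnames(X_nui), colnames(X))
  )
  structure(list(X = X, groups = groups, run_rows = run_rows,
                 TR = TR, run_len = run_len, k = k,
                 split_by = split_by, modulator = modulator,
                 cells = table(cell)),
            class = "grid_design",
            unidentifiable = unidentifiable)
}

#' @export
print.grid_design <- function(x, ...) {
  cat("<grid_design>", nrow(x$X), "scans x", ncol(x$X), "columns; k =", x$k,
      "; split:", x$split_by, "; modulators:", x$modulator, "\n")
  invisible(x)
}

#' Export a design matrix as TSV
#' @param design a \code{grid_design}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design$X), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
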