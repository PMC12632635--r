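#' Task configuration
#'
#' Parameters of the predictive-inference ("shield") task: participants move a
#' colored shield to block attacks drawn from an isotropic 2D Gaussian centered
#' on a color-specific target location on a circular arena. All geometry is in
#' screen pixels with the origin at the arena center.
#'
#' @param planet_radius arena radius in pixels.
#' @param n_colors number of original shield colors.
#' @param attack_sd per-axis SD of attack scatter, as a fraction of
#'   \code{planet_radius}.
#' @param target_radius_bounds lower/upper bound on target radial position as
#'   fractions of \code{planet_radius}.
#' @param sim_period_choices possible simulation-period durations (seconds);
#'   drawn uniformly per trial.
#' @param response_period response-period duration (seconds).
#' @param outcome_period outcome-period duration (seconds).
#' @param iti_period inter-trial gap (seconds).
#' @param correct_threshold absolute angular error (degrees) below which a
#'   response counts as correct.
#' @param missed_threshold minimum shield movement (pixels); smaller movements
#'   are classified as missed regardless of angular error.
#' @param color_lab optional matrix (one row per color) of CIELAB triplets used
#'   for perceptual-distance covariates; defaults to an iso-luminant hue circle.
#' @return an object of class \code{task_config} (a named list).
#' @export
task_config <- function(planet_radius = 500,
                        n_colors = 5,
                        attack_sd = 0.04,
                        target_radius_bounds = c(0.20, 0.80),
                        sim_period_choices = 2:6,
                        response_period = 3,
                        outcome_period = 1,
                        iti_period = 1,
                        correct_threshold = 45,
                        missed_threshold = 10,
                        color_lab = NULL) {
  stopifnot(planet_radius > 0, n_colors >= 1, attack_sd > 0)
  if (!(length(target_radius_bounds) == 2 &&
        0 < target_radius_bounds[1] &&
        target_radius_bounds[1] < target_radius_bounds[2] &&
        target_radius_bounds[2] < 1)) {
    stop("target_radius_bounds must satisfy 0 < lower < upper < 1", call. = FALSE)
  }
  if (length(sim_period_choices) == 0 ||
      any(sim_period_choices != round(sim_period_choices))) {
    stop("sim_period_choices must be a nonempty set of integer seconds", call. = FALSE)
  }
  if (is.null(color_lab)) color_lab <- color_lab_palette(n_colors)
  cfg <- list(
    planet_radius = planet_radius,
    n_colors = as.integer(n_colors),
    attack_sd = attack_sd,
    target_radius_bounds = target_radius_bounds,
    sim_period_choices = as.integer(sim_period_choices),
    response_period = response_period,
    outcome_period = outcome_period,
    iti_period = iti_period,
    correct_threshold = correct_threshold,
    missed_threshold = missed_threshold,
    color_lab = color_lab
  )
  class(cfg) <- "task_config"
  cfg
}

#' CIELAB triplets on an iso-luminant hue circle
#'
#' Deterministic per-color CIELAB coordinates (L* = 60, chroma 50) used for the
#' perceptual color-distance covariate when no measured values are supplied.
#'
#' @param n number of colors.
#' @return an n x 3 matrix with columns L, a, b.
#' @export
color_lab_palette <- function(n) {
  ang <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  cbind(L = rep(60, n), a = 50 * cos(ang), b = 50 * sin(ang))
}

#' Sample color target locations
#'
#' Draws one target location per color: polar angle uniform on [0, 360) and
#' radius uniform between the configured radial bounds (strictly inside
#' (0.2 R, 0.8 R) by default, keeping angular error meaningful and away from
#' the arena edge).
#'
#' @param config a \code{\link{task_config}}.
#' @param seed integer seed; the same seed reproduces the same targets.
#' @param n_colors number of targets to draw (defaults to
#'   \code{config$n_colors}).
#' @return data.frame with columns \code{color}, \code{x}, \code{y}.
#' @export
sample_target_locations <- function(config, seed = NULL, n_colors = config$n_colors) {
  R <- config$planet_radius
  b <- config$target_radius_bounds
  with_seed(seed, {
    ang <- runif(n_colors, 0, 360)
    rad <- runif(n_colors, b[1] * R, b[2] * R)
    data.frame(
      color = seq_len(n_colors),
      x = rad * cos(deg2rad(ang)),
      y = rad * sin(deg2rad(ang))
    )
  })
}

#' Rotate target locations about the arena center
#'
#' @param targets data.frame with \code{x}, \code{y} columns (any extra columns
#'   are preserved).
#' @param angle_deg rotation angle in degrees, counterclockwise positive.
#' @return the rotated targets; radii are preserved exactly.
#' @export
rotate_targets <- function(targets, angle_deg) {
  stopifnot(is.finite(angle_deg))
  a <- deg2rad(angle_deg)
  x <- targets$x * cos(a) - targets$y * sin(a)
  y <- targets$x * sin(a) + targets$y * cos(a)
  targets$x <- x
  targets$y <- y
  targets
}

#' Sample an attack location
#'
#' Attack outcomes are drawn from an isotropic two-dimensional Gaussian
#' centered on the target, with per-axis SD equal to
#' \code{attack_sd * planet_radius}.
#'
#' @param target length-2 numeric (x, y) or a one-row data.frame.
#' @param config a \code{\link{task_config}}.
#' @param seed optional integer seed.
#' @param n number of draws.
#' @return an n x 2 matrix of attack coordinates.
#' @export
sample_attack <- function(target, config, seed = NULL, n = 1) {
  if (is.data.frame(target)) target <- c(target$x[1], target$y[1])
  sdev <- config$attack_sd * config$planet_radius
  with_seed(seed, cbind(
    x = rnorm(n, target[1], sdev),
    y = rnorm(n, target[2], sdev)
  ))
}

#' Candidate rotation set for the novel-rotations session
#'
#' The 23 rotations from 15 to 345 degrees in 15-degree steps.
#' @return integer vector of length 23.
#' @export
rotation_candidates <- function() as.integer(seq(15, 345, by = 15))

# Core schedule builder shared by the three sessions and by simulation-scale
# schedules. `rotations` is the absolute rotation of each state-block with
# respect to the original configuration; `novel_plan` (session 2) is a list
# with one integer vector of novel color ids per state-block.
make_schedule <- function(rotations, n_miniblocks, config, seed = NULL,
                          n_runs = 1, novel_plan = NULL, session_id = NA_integer_) {
  n_blocks <- length(rotations)
  if (n_blocks %% n_runs != 0) {
    stop("number of state-blocks must be divisible by n_runs", call. = FALSE)
  }
  blocks_per_run <- n_blocks %/% n_runs
  with_seed(seed, {
    rows <- vector("list", n_blocks * n_miniblocks)
    i <- 0L
    for (b in seq_len(n_blocks)) {
      for (m in seq_len(n_miniblocks)) {
        colors <- sample(config$n_colors)           # each original color once
        novel <- rep(FALSE, length(colors))
        if (!is.null(novel_plan)) {
          nv <- novel_plan[[b]]
          colors <- c(colors, sample(nv))            # novel trials appended
          novel <- c(novel, rep(TRUE, length(nv)))
        }
        i <- i + 1L
        rows[[i]] <- data.frame(
          state_block = b,
          miniblock = m,
          trial_in_miniblock = seq_along(colors),
          color = colors,
          novel = novel,
          rotation = rotations[b]
        )
      }
    }
    trials <- do.call(rbind, rows)
    n <- nrow(trials)
    trials$trial <- seq_len(n)
    trials$run <- ((trials$state_block - 1L) %/% blocks_per_run) + 1L
    choices <- config$sim_period_choices        # safe for length-1 choice sets
    trials$sim_dur <- choices[sample.int(length(choices), n, replace = TRUE)]

    # sequential timing within each run, with a short lead-in
    trials$onset_sim <- NA_real_
    for (r in seq_len(n_runs)) {
      idx <- which(trials$run == r)
      trial_len <- trials$sim_dur[idx] + config$response_period +
        config$outcome_period + config$iti_period
      trials$onset_sim[idx] <- 4 + c(0, cumsum(trial_len[-length(trial_len)]))
    }
    trials$onset_resp <- trials$onset_sim + trials$sim_dur
    trials$onset_out <- trials$onset_resp + config$response_period
    run_dur <- vapply(seq_len(n_runs), function(r) {
      idx <- trials$run == r
      max(trials$onset_out[idx] + config$outcome_period) + 10
    }, numeric(1))

    trials <- trials[, c("trial", "run", "state_block", "miniblock",
                         "trial_in_miniblock", "color", "novel", "rotation",
                         "sim_dur", "onset_sim", "onset_resp", "onset_out")]
    structure(trials,
              class = c("session_schedule", "data.frame"),
              session_id = session_id,
              config = config,
              rotations = rotations,
              n_runs = n_runs,
              run_dur = run_dur,
              seed = seed)
  })
}

#' Build a session schedule
#'
#' Generates the trial schedule for one of the three task sessions:
#' \describe{
#'   \item{Session 1 (training)}{8 state-blocks of 8 mini-blocks; the 5 color
#'     targets rotate by +90 then -90 degrees at alternate state changes, so
#'     absolute rotations alternate 0/90. 320 trials.}
#'   \item{Session 2 (novel colors, scanner)}{8 state-blocks of 6 mini-blocks
#'     with the same alternating 0/90 rotations, split over 4 runs. Each
#'     mini-block presents the 5 original colors followed by 2 novel-color
#'     trials; each of 8 novel colors is active in exactly two state-blocks
#'     (training block, then its inferential-test block in the other rotation).
#'     The naive total is 336 trials; the published session total (332) is not
#'     derivable from the block structure, so the discrepancy is recorded in
#'     \code{attr(, "printed_trial_total")}.}
#'   \item{Session 3 (novel rotations)}{8 state-blocks of 8 mini-blocks; block
#'     1 is the original configuration and blocks 2-8 draw unique rotations
#'     without replacement from the 23-member 15-degree-step candidate set.
#'     320 trials.}
#' }
#'
#' @param session_id 1, 2 or 3.
#' @param config a \code{\link{task_config}}.
#' @param seed integer seed; identical (session, config, seed) give identical
#'   schedules.
#' @param n_runs number of scanner runs (default 4 for session 2, 1 otherwise).
#' @return a \code{session_schedule}: a data.frame of trial slots with indices,
#'   color, novel flag, per-block rotation and phase onsets/durations, plus
#'   attributes (\code{config}, \code{rotations}, \code{n_runs},
#'   \code{run_dur}, and for session 3 \code{candidate_rotations}).
#' @export
build_session_schedule <- function(session_id, config = task_config(), seed = NULL,
                                   n_runs = if (session_id == 2) 4 else 1) {
  if (!session_id %in% 1:3) {
    stop("unknown session id: ", session_id, " (must be 1, 2 or 3)", call. = FALSE)
  }
  seeds <- if (is.null(seed)) {
    list(rotations = NULL, trials = NULL)
  } else {
    as.list(derive_seeds(seed, 2, c("rotations", "trials")))
  }

  if (session_id == 1) {
    sched <- make_schedule(rep(c(0, 90), 4), 8, config, seed = seed,
                           n_runs = n_runs, session_id = 1L)
  } else if (session_id == 2) {
    # 8 novel colors, ids n_colors+1 .. n_colors+8; color j active in blocks
    # (j, j+1) for j = 1..7 and color 8 in blocks (1, 8): every block hosts
    # exactly two novel colors and every color is trained in one rotation and
    # tested in the other.
    nv <- config$n_colors + 1:8
    plan <- lapply(1:8, function(b) {
      act <- nv[c(if (b <= 7) b, if (b >= 2) b - 1, if (b %in% c(1, 8)) 8)]
      unique(act)[1:2]
    })
    sched <- make_schedule(rep(c(0, 90), 4), 6, config, seed = seed,
                           n_runs = n_runs, novel_plan = plan, session_id = 2L)
    attr(sched, "printed_trial_total") <- 332L
    attr(sched, "novel_colors") <- nv
  } else {
    cand <- rotation_candidates()
    rots <- c(0L, with_seed(seeds[["rotations"]], sample(cand, 7)))
    sched <- make_schedule(rots, 8, config, seed = seeds[["trials"]],
                           n_runs = n_runs, session_id = 3L)
    attr(sched, "candidate_rotations") <- cand
  }
  sched
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("<session_schedule> session", attr(x, "session_id"), "-",
      nrow(x), "trials,",
      length(attr(x, "rotations")), "state-blocks,",
      attr(x, "n_runs"), "run(s)\n")
  cat("  state-block rotations (deg):",
      paste(attr(x, "rotations"), collapse = " "), "\n")
  invisible(x)
}

# Absolute rotation of the alternate state for each trial: sessions 1/2 use the
# other member of {0, 90}; session 3 uses the previous state-block's rotation
# (NA for block 1, where no alternate configuration has been experienced).
alt_rotation <- function(schedule) {
  session <- attr(schedule, "session_id")
  rots <- attr(schedule, "rotations")
  if (!is.na(session) && session == 3) {
    prev <- c(NA_real_, rots[-length(rots)])
    prev[schedule$state_block]
  } else {
    ifelse(schedule$rotation == 0, 90, 0)
  }
}
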