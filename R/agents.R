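#' Simulate an agent performing the task
#'
#' Plays a schedule with one of several response strategies and returns a
#' complete behavioral dataset: start/response/attack positions, the angle of
#' travel theta (direction of the vector from the shield start position to the
#' final response position), and trial labels (see
#' \code{\link{classify_trials}}).
#'
#' Strategies:
#' \describe{
#'   \item{random}{responds at a uniformly random polar angle (radius = half
#'     the arena radius); the chance baseline.}
#'   \item{persistent}{always responds at the alternate (previous) state's
#'     target position for the trial color, i.e. never updates after a state
#'     change.}
#'   \item{transfer_learner}{knows the original-configuration target of every
#'     color; on the first trial of a new state-block it responds using its
#'     current rotation estimate (carried over from the previous block), then
#'     infers the new rotation from that trial's attack location and applies
#'     it to all colors - single-observation (zero-shot) transfer. Optional
#'     \code{response_noise} (degrees, SD of von-Mises-free Gaussian angular
#'     noise) perturbs responses.}
#'   \item{noisy_learner}{alias for transfer_learner with
#'     \code{response_noise = 20} unless overridden.}
#' }
#'
#' @param schedule a \code{session_schedule}.
#' @param agent_spec a strategy name, or \code{list(type =, ...)} with
#'   parameters (\code{response_noise} in degrees).
#' @param config the \code{\link{task_config}} (defaults to the schedule's).
#' @param seed integer seed; (schedule, agent, seed) reproduce the dataset.
#' @param targets optional data.frame of original-state targets (color, x, y);
#'   sampled from \code{config} if missing.
#' @return a \code{behavioral_dataset}: the schedule data.frame augmented with
#'   positions, \code{theta}, targets for the current and alternate states and
#'   labels; attributes carry config, agent, targets and seed.
#' @export
simulate_agent <- function(schedule, agent_spec = "random",
                           config = attr(schedule, "config"),
                           seed = NULL, targets = NULL) {
  if (is.character(agent_spec)) agent_spec <- list(type = agent_spec)
  type <- agent_spec$type
  known <- c("random", "persistent", "transfer_learner", "noisy_learner")
  if (is.null(type) || !type %in% known) {
    stop("unknown agent type: ", deparse(type),
         " (expected one of ", paste(known, collapse = ", "), ")", call. = FALSE)
  }
  if (type == "noisy_learner") {
    agent_spec$response_noise <- agent_spec$response_noise %||% 20
    type <- "transfer_learner"
  }
  resp_noise <- agent_spec$response_noise %||% 0
  R <- config$planet_radius

  seeds <- if (is.null(seed)) list(targets = NULL, play = NULL) else
    as.list(derive_seeds(seed, 2, c("targets", "play")))
  n_colors_total <- max(schedule$color)
  if (is.null(targets)) {
    targets <- sample_target_locations(config, seeds$targets,
                                       n_colors = n_colors_total)
  }

  ev <- as.data.frame(schedule)
  n <- nrow(ev)
  alt_rot <- alt_rotation(schedule)

  # current / alternate state target per trial
  tc <- ta <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    tg <- targets[targets$color == ev$color[i], , drop = FALSE]
    cur <- rotate_targets(tg, ev$rotation[i])
    tc[i, ] <- c(cur$x, cur$y)
    if (!is.na(alt_rot[i])) {
      alt <- rotate_targets(tg, alt_rot[i])
      ta[i, ] <- c(alt$x, alt$y)
    }
  }

  out <- with_seed(seeds$play, {
    # start positions uniform over the arena disc
    u <- runif(n); sa <- runif(n, 0, 360)
    start <- cbind(R * sqrt(u) * cos(deg2rad(sa)), R * sqrt(u) * sin(deg2rad(sa)))
    attack <- tc + matrix(rnorm(2 * n, 0, config$attack_sd * R), n, 2)

    resp <- matrix(NA_real_, n, 2)
    if (type == "random") {
      ra <- runif(n, 0, 360)
      resp <- 0.5 * R * cbind(cos(deg2rad(ra)), sin(deg2rad(ra)))
    } else if (type == "persistent") {
      resp <- ta
      first_block <- ev$state_block == 1
      resp[first_block, ] <- tc[first_block, ]
    } else { # transfer_learner
      rot_est <- ev$rotation[1]                  # trained on the first block
      for (i in seq_len(n)) {
        tg <- targets[targets$color == ev$color[i], c("x", "y")]
        pred <- rotate_targets(tg, rot_est)
        ang <- point_angle(pred$x, pred$y)
        if (resp_noise > 0) ang <- ang + rnorm(1, 0, resp_noise)
        rad <- sqrt(pred$x^2 + pred$y^2)
        resp[i, ] <- rad * c(cos(deg2rad(ang)), sin(deg2rad(ang)))
        # feedback: infer the block rotation from the observed attack
        tg_ang <- point_angle(tg$x, tg$y)
        at_ang <- point_angle(attack[i, 1], attack[i, 2])
        rot_est <- wrap_angle(at_ang - tg_ang)
      }
    }
    list(start = start, attack = attack, resp = resp)
  })

  ev$start_x <- out$start[, 1]; ev$start_y <- out$start[, 2]
  ev$resp_x <- out$resp[, 1];  ev$resp_y <- out$resp[, 2]
  ev$attack_x <- out$attack[, 1]; ev$attack_y <- out$attack[, 2]
  ev$target_curr_x <- tc[, 1]; ev$target_curr_y <- tc[, 2]
  ev$target_alt_x <- ta[, 1];  ev$target_alt_y <- ta[, 2]
  ev$movement <- euclid(ev$start_x, ev$start_y, ev$resp_x, ev$resp_y)
  # angle of travel: start -> final response; degenerate zero-length movement
  # gets theta = 0 (such trials are flagged missed by the movement threshold)
  ev$theta <- wrap_angle(rad2deg(atan2(ev$resp_y - ev$start_y,
                                       ev$resp_x - ev$start_x)))
  ev$theta[ev$movement == 0] <- 0

  ds <- structure(ev,
                  class = c("behavioral_dataset", "data.frame"),
                  config = config,
                  schedule_attrs = attributes(schedule)[c("session_id", "rotations",
                                                          "n_runs", "run_dur")],
                  agent = agent_spec,
                  targets = targets,
                  seed = seed)
  classify_trials(ds, config)
}

#' @export
print.behavioral_dataset <- function(x, ...) {
  ag <- attr(x, "agent")
  cat("<behavioral_dataset>", nrow(x), "trials; agent:",
      ag$type %||% "?", "\n")
  if (!is.null(x$normalized_error)) {
    cat("  mean normalized error:",
        round(mean(x$normalized_error, na.rm = TRUE), 3),
        "| correct:", sum(x$correct, na.rm = TRUE),
        "| missed:", sum(x$missed), "\n")
  }
  invisible(x)
}
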