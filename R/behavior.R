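#' Normalized angular error
#'
#' The angular error of a response toward the current-state target, normalized
#' by the summed angular errors toward the current- and alternate-state
#' targets:
#' \deqn{e = \theta_{curr} / (\theta_{alt} + \theta_{curr})}
#' where each term is the minimal angular distance (about the arena center)
#' between the response's polar angle and the respective target's polar angle.
#' 0 means a response exactly at the current target's angle, 1 exactly at the
#' alternate target's angle, and 0.5 a response equidistant between the two.
#'
#' @param response_pos,target_curr,target_alt two-column matrices (or length-2
#'   vectors) of screen coordinates.
#' @param center arena center (default origin).
#' @return numeric vector of normalized errors in [0, 1].
#' @export
normalized_error <- function(response_pos, target_curr, target_alt,
                             center = c(0, 0)) {
  as_mat <- function(p) if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  rp <- as_mat(response_pos); tc <- as_mat(target_curr); ta <- as_mat(target_alt)
  ra <- point_angle(rp[, 1], rp[, 2], center)
  ca <- point_angle(tc[, 1], tc[, 2], center)
  aa <- point_angle(ta[, 1], ta[, 2], center)
  ec <- angular_distance(ra, ca)
  ea <- angular_distance(ra, aa)
  denom <- ec + ea
  if (any(denom == 0, na.rm = TRUE)) {
    stop("normalized error undefined: response lies exactly at the shared ",
         "angle of both targets", call. = FALSE)
  }
  ec / denom
}

#' Classify trials and attach behavioral error measures
#'
#' Adds to a behavioral dataset: \code{abs_angular_error} (angular distance,
#' about the center, between response and current target, in [0, 180]),
#' \code{theta_curr_error} / \code{theta_alt_error}, \code{normalized_error},
#' and the labels \code{correct} (absolute angular error under the configured
#' threshold, default 45 degrees), \code{missed} (shield moved less than the
#' movement threshold, default 10 px, regardless of error), \code{transfer}
#' (trials 2-5 of the first mini-block after a state change, original colors)
#' and \code{novel_transfer} (first presentation of a novel color in its
#' rotated, inferential-test state-block).
#'
#' @param dataset a \code{behavioral_dataset} (or data.frame with the position
#'   columns populated).
#' @param config a \code{\link{task_config}}.
#' @return the dataset with label columns added/refreshed.
#' @export
classify_trials <- function(dataset, config = attr(dataset, "config")) {
  ev <- dataset
  ra <- point_angle(ev$resp_x, ev$resp_y)
  ca <- point_angle(ev$target_curr_x, ev$target_curr_y)
  ev$abs_angular_error <- angular_distance(ra, ca)
  has_alt <- !is.na(ev$target_alt_x)
  aa <- point_angle(ev$target_alt_x, ev$target_alt_y)
  ev$theta_curr_error <- ev$abs_angular_error
  ev$theta_alt_error <- ifelse(has_alt, angular_distance(ra, aa), NA_real_)
  denom <- ev$theta_curr_error + ev$theta_alt_error
  ev$normalized_error <- ifelse(has_alt & denom > 0,
                                ev$theta_curr_error / denom, NA_real_)

  ev$missed <- ev$movement < config$missed_threshold
  ev$correct <- !ev$missed & ev$abs_angular_error < config$correct_threshold

  ev$transfer <- !ev$novel &
    ev$state_block > 1 &
    ev$miniblock == 1 &
    ev$trial_in_miniblock >= 2 & ev$trial_in_miniblock <= 5

  ev$novel_transfer <- FALSE
  if (any(ev$novel)) {
    for (cl in unique(ev$color[ev$novel])) {
      idx <- which(ev$color == cl)
      blocks <- sort(unique(ev$state_block[idx]))
      if (length(blocks) >= 2) {
        test_block <- blocks[2]
        first <- idx[ev$state_block[idx] == test_block][1]
        ev$novel_transfer[first] <- TRUE
      }
    }
  }
  ev
}

#' Condition label used in GLMs
#'
#' correct / incorrect / missed factor per trial (missed takes precedence).
#' @param events a classified behavioral dataset.
#' @return factor with levels correct, incorrect, missed.
#' @export
trial_condition <- function(events) {
  factor(ifelse(events$missed, "missed",
                ifelse(events$correct, "correct", "incorrect")),
         levels = c("correct", "incorrect", "missed"))
}

#' Random-response null distribution for transfer-trial error
#'
#' Simulates a guessing strategy on a dataset's transfer trials: in each
#' simulation every transfer trial receives a uniformly random response angle,
#' and the mean absolute angular error (response vs. current target, in
#' [0, 180]) across transfer trials is recorded. The 2.5th and 97.5th
#' percentiles of the simulated means form the 95\% confidence interval
#' against which an observed mean error can be compared.
#'
#' @param dataset a classified behavioral dataset (or any data.frame with
#'   \code{transfer} and current-target columns).
#' @param n_sims number of simulated means (>= 2; 1000 in typical use).
#' @param seed integer seed.
#' @param use_trials which trials to simulate over: "transfer" (default),
#'   "novel_transfer" or "all".
#' @return an object of class \code{null_distribution} with elements
#'   \code{samples}, \code{ci_low}, \code{ci_high}, \code{n_sims},
#'   \code{n_trials}.
#' @export
random_response_null <- function(dataset, n_sims = 1000, seed = NULL,
                                 use_trials = c("transfer", "novel_transfer", "all")) {
  stopifnot(n_sims >= 2)
  use_trials <- match.arg(use_trials)
  keep <- switch(use_trials,
                 transfer = dataset$transfer,
                 novel_transfer = dataset$novel_transfer,
                 all = rep(TRUE, nrow(dataset)))
  tgt <- dataset[keep, c("target_curr_x", "target_curr_y")]
  n_tr <- nrow(tgt)
  if (n_tr == 0) stop("no transfer trials in dataset", call. = FALSE)
  ca <- point_angle(tgt$target_curr_x, tgt$target_curr_y)
  samples <- with_seed(seed, {
    err <- matrix(angular_distance(runif(n_sims * n_tr, 0, 360),
                                   rep(ca, each = n_sims)),
                  nrow = n_sims)
    rowMeans(err)
  })
  ci <- unname(stats::quantile(samples, c(0.025, 0.975)))
  structure(list(samples = samples, ci_low = ci[1], ci_high = ci[2],
                 n_sims = n_sims, n_trials = n_tr),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution>", x$n_sims, "simulated means over", x$n_trials,
      "trials\n  mean", round(mean(x$samples), 2),
      " 95% CI [", round(x$ci_low, 2), ",", round(x$ci_high, 2), "]\n")
  invisible(x)
}

#' Rank-ordered guessing null for a cohort
#'
#' Simulates whole cohorts of guessing participants (each participant's mean
#' absolute angular error over \code{n_trials} uniformly random responses),
#' sorts the cohort means ascending within each simulation, and returns the
#' 95\% CI of each rank's order statistic. Observed participants, rank-ordered
#' by their error, can be compared rank-by-rank against this null.
#'
#' @param n_participants cohort size.
#' @param n_trials trials per participant.
#' @param n_sims number of simulated cohorts.
#' @param seed integer seed.
#' @return data.frame with columns \code{rank}, \code{mean}, \code{ci_low},
#'   \code{ci_high}.
#' @export
rank_order_guessing_null <- function(n_participants, n_trials, n_sims = 1000,
                                     seed = NULL) {
  stopifnot(n_participants >= 1, n_trials >= 1, n_sims >= 1)
  sorted <- with_seed(seed, {
    m <- matrix(runif(n_sims * n_participants * n_trials, 0, 180),
                nrow = n_sims * n_participants)
    means <- matrix(rowMeans(m), nrow = n_sims)
    t(apply(means, 1, sort))
  })
  if (n_participants == 1) sorted <- matrix(sorted, ncol = 1)
  data.frame(
    rank = seq_len(n_participants),
    mean = colMeans(sorted),
    ci_low = apply(sorted, 2, stats::quantile, 0.025),
    ci_high = apply(sorted, 2, stats::quantile, 0.975)
  )
}

#' Logit transform for bounded error measures
#'
#' log(v / (1 - v)) after clipping values into [eps, 1 - eps] so that errors
#' of exactly 0 or 1 stay finite.
#'
#' @param values numeric in [0, 1].
#' @param eps clipping bound (default 1e-3).
#' @return transformed values.
#' @export
logit_error <- function(values, eps = 1e-3) {
  v <- pmin(pmax(values, eps), 1 - eps)
  log(v / (1 - v))
}

# ---- two-stage (subject OLS -> group t) machinery -------------------------

# Per-subject OLS with an informative error on rank deficiency.
subject_ols <- function(X, y, terms) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(qr.coef(qrX, y), colnames(X))
}

#' Group-level one-sample t-tests on per-subject coefficients
#'
#' The second stage of the two-stage scheme: a coefficient matrix with one row
#' per subject is tested column-wise against zero.
#'
#' @param coefs matrix (subjects x terms) of per-subject coefficients.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return data.frame with term, mean, t, df, p and Cohen's d (mean/SD).
#' @export
group_coefficient_test <- function(coefs, alternative = "two.sided") {
  coefs <- as.matrix(coefs)
  if (nrow(coefs) < 2) stop("group test requires >= 2 subjects", call. = FALSE)
  res <- lapply(colnames(coefs), function(tm) {
    x <- coefs[, tm]
    tt <- stats::t.test(x, mu = 0, alternative = alternative)
    data.frame(term = tm, mean = mean(x), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               d = mean(x) / stats::sd(x))
  })
  do.call(rbind, res)
}

#' Multi-timescale regression of normalized error
#'
#' Per-subject OLS of normalized error on timescale regressors, followed by
#' group-level two-tailed one-sample t-tests on the coefficients. Two levels
#' mirror the standard behavioral analyses:
#' \describe{
#'   \item{trial_within_first_miniblock}{restricted to the first mini-block
#'     after each state change (state-blocks >= 2): regressors for trial
#'     number within the mini-block, block number, and their interaction.}
#'   \item{miniblock}{all mini-blocks: regressors for mini-block number, block
#'     number, and their interaction.}
#' }
#' Predictors are mean-centered within subject before forming the interaction;
#' missed trials are excluded (no meaningful response position).
#'
#' @param datasets a classified \code{behavioral_dataset} or a list of them
#'   (one per subject).
#' @param level which timescale model to fit.
#' @return an object of class \code{group_regression}: list with
#'   \code{subject_coefs} (subjects x terms) and \code{group} (the t table).
#' @export
multi_timescale_regression <- function(datasets,
                                       level = c("trial_within_first_miniblock",
                                                 "miniblock")) {
  level <- match.arg(level)
  if (is.data.frame(datasets)) datasets <- list(datasets)
  coefs <- t(vapply(datasets, function(ev) {
    ev <- ev[!ev$missed & !is.na(ev$normalized_error), ]
    if (level == "trial_within_first_miniblock") {
      ev <- ev[ev$miniblock == 1 & ev$state_block > 1 & !ev$novel, ]
      a <- ev$trial_in_miniblock; b <- ev$state_block
      nm <- c("trial", "block", "trial:block")
    } else {
      a <- ev$miniblock; b <- ev$state_block
      nm <- c("miniblock", "block", "miniblock:block")
    }
    ac <- a - mean(a); bc <- b - mean(b)
    X <- cbind("(Intercept)" = 1, ac, bc, ac * bc)
    colnames(X) <- c("(Intercept)", nm)
    subject_ols(X, ev$normalized_error, nm)
  }, numeric(4)))
  structure(list(subject_coefs = coefs,
                 group = if (nrow(coefs) >= 2) group_coefficient_test(coefs) else NULL,
                 level = level),
            class = "group_regression")
}

#' @export
print.group_regression <- function(x, ...) {
  cat("<group_regression> level:", x$level, "-",
      nrow(x$subject_coefs), "subject(s)\n")
  if (!is.null(x$group)) {
    print(x$group, row.names = FALSE, digits = 3)
  } else {
    cat("  (single subject; coefficients only)\n")
    print(round(x$subject_coefs, 4))
  }
  invisible(x)
}
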