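test_that("grid angle estimation matches a brute-force fit oracle", {
  # direct anchors of the atan2 rule
  expect_equal(estimate_grid_angle(0, 1, 6), 0)
  expect_equal(estimate_grid_angle(1, 0, 6), 15)

  # brute-force oracle: the phi maximizing the fit of
  # beta_sin*sin(6t)+beta_cos*cos(6t) by cos(6[t - phi])
  brute_phi <- function(bs, bc, k = 6) {
    th <- seq(0, 359.9, by = 0.5)
    target <- bs * sin(k * th * pi / 180) + bc * cos(k * th * pi / 180)
    grid <- seq(0, 360 / k, by = 0.001)
    fit <- vapply(grid, function(p) {
      pred <- cos(k * (th - p) * pi / 180)
      sum(pred * target)
    }, numeric(1))
    grid[which.max(fit)]
  }
  expect_equal(estimate_grid_angle(-1, 0, 6), 45)
  expect_equal(brute_phi(-1, 0), 45, tolerance = 0.01)
  set.seed(11)
  for (i in 1:5) {
    bs <- rnorm(1); bc <- rnorm(1)
    expect_equal(estimate_grid_angle(bs, bc, 6), brute_phi(bs, bc),
                 tolerance = 0.01)
  }
  expect_error(estimate_grid_angle(0, 0, 6), "unidentifiable")
})

test_that("angle differences live on the k-fold circle", {
  expect_equal(angle_difference(10, 40, 6), 30)      # the maximal distance
  expect_equal(angle_difference(5, 65, 6), 0)        # a full period apart
  expect_equal(angle_difference(59, 1, 6), 2)        # across the wrap
  expect_equal(angle_difference(0, 45, 4), 45)
  # periodicities of the fold set
  expect_equal(360 / c(4, 5, 6, 7, 8), c(90, 72, 60, 360 / 7, 45))
  expect_equal(round(360 / 7, 1), 51.4)
})

test_that("circular mean averages on the k-fold circle, not arithmetically", {
  expect_equal(circular_mean_angle(c(58, 2), 6), 0)    # wraps at 60
  expect_equal(circular_mean_angle(c(10, 20), 6), 15)
  expect_equal(circular_mean_angle(rep(33, 5), 6), 33)
})

test_that("grid orientation is recovered within 3 degrees at SNR 1", {
  errs <- vapply(1:5, function(s) {
    sub <- sim_subject(500 + s, regime = "spatial", grid_phi = 37,
                       amplitude = 1, noise_sd = 1)
    gf <- grid_glm(sub$bold)
    max(angle_difference(gf$angles$phi, 37, 6))
  }, numeric(1))
  expect_lt(max(errs), 3)
})

test_that("between-state coefficients separate cognitive from spatial codes", {
  res <- vapply(1:6, function(s) {
    cg <- between_state_crossval(sim_subject(600 + s, "cognitive")$bold)
    sp <- between_state_crossval(sim_subject(700 + s, "spatial")$bold)
    c(cg$mean, sp$mean)
  }, numeric(2))
  expect_true(all(res[1, ] < 0))     # cognitive: antiphase, negative
  expect_true(all(res[2, ] > 0))     # spatial: in-phase, positive

  # permuted angles of travel destroy the effect
  sub <- sim_subject(801, "cognitive")
  ev <- sub$bold$events
  ev$theta <- gridshift:::with_seed(802, sample(ev$theta))
  cv0 <- between_state_crossval(sub$bold, ev)
  expect_lt(abs(cv0$mean), 0.25)
})

test_that("between-state cross-validation needs two identifiable states", {
  cfg <- task_config()
  sched <- gridshift:::make_schedule(c(0, 0), 4, cfg, seed = 1, n_runs = 2)
  beh <- simulate_agent(sched, "transfer_learner", cfg, seed = 2)
  bold <- simulate_bold(beh, bold_sim_config(regime = "spatial"), seed = 3)
  expect_error(between_state_crossval(bold), ">= 2 states")
})

test_that("within-state cross-validation rewards stable orientations only", {
  # stable planted orientation: positive coefficients, near the amplitude
  sub <- sim_subject(901, regime = "spatial", noise_sd = 0)
  cw0 <- within_state_crossval(sub$bold)
  expect_equal(unname(cw0$mean), 1, tolerance = 0.01)

  sub1 <- sim_subject(902, regime = "spatial", noise_sd = 1)
  cw <- within_state_crossval(sub1$bold)
  expect_gt(cw$mean, 0.5)

  # orientation redrawn uniformly per run: the predicted-modulator
  # coefficients are cos(k[phi_run - loo mean]) with random phases and
  # collapse toward zero on average (pooled over replicate datasets)
  cfg <- task_config()
  stitch <- function(seed) {
    seeds <- gridshift:::derive_seeds(seed, 7)
    sched <- sim_schedule(seeds[1], n_blocks = 8, n_miniblocks = 6, n_runs = 4)
    beh <- simulate_agent(sched, "transfer_learner", cfg, seed = seeds[2])
    phis <- gridshift:::with_seed(seeds[7], runif(4, 0, 60))
    per_run <- lapply(1:4, function(r) {
      ev_r <- beh[beh$run == r, ]
      ev_r$run <- 1L
      attr(ev_r, "schedule_attrs") <- list(run_dur = attr(sched, "run_dur")[r])
      simulate_bold(ev_r, bold_sim_config(regime = "spatial",
                                          grid_phi = phis[r], noise_sd = 1),
                    seed = seeds[2 + r])
    })
    stitched <- per_run[[1]]
    stitched$signal <- do.call(cbind, lapply(per_run, `[[`, "signal"))
    stitched$run_len <- vapply(per_run, function(b) as.integer(b$run_len),
                               integer(1))
    stitched$nuisance <- do.call(rbind, lapply(per_run, `[[`, "nuisance"))
    stitched$events <- beh
    stitched
  }
  pooled <- unlist(lapply(1:4, function(rep) {
    within_state_crossval(stitch(903 + rep))$coefficients
  }))
  expect_lt(abs(mean(pooled)), 0.4)
  expect_lt(abs(mean(pooled)), cw$mean / 2)   # far below the stable case

  one_run <- stitch(950)
  one_run$signal <- one_run$signal[, 1:one_run$run_len[1], drop = FALSE]
  one_run$run_len <- one_run$run_len[1]
  one_run$events <- one_run$events[one_run$events$run == 1, ]
  one_run$nuisance <- one_run$nuisance[1:one_run$run_len, , drop = FALSE]
  expect_error(within_state_crossval(one_run), ">= 2 runs")
})

test_that("fold-symmetry scan flags only the planted symmetry", {
  sub <- sim_subject(1001, regime = "cognitive", amplitude = 1.5,
                     noise_sd = 1)
  fs <- fold_symmetry_scan(sub$bold, folds = c(4, 6, 8), mode = "between")
  ms <- setNames(fs$summary$mean_coefficient, paste0("k", fs$summary$fold))
  expect_lt(ms["k6"], -0.5)
  expect_lt(max(abs(ms[c("k4", "k8")])), 0.4)

  # a planted four-fold spatial code shows up only at k = 4 (within mode)
  sub4 <- sim_subject(1002, regime = "spatial", noise_sd = 0.5, fold_k = 4)
  fs4 <- fold_symmetry_scan(sub4$bold, folds = c(4, 6), mode = "within")
  m4 <- setNames(fs4$summary$mean_coefficient, paste0("k", fs4$summary$fold))
  expect_gt(m4["k4"], 0.5)
  expect_lt(abs(m4["k6"]), 0.4)
})

test_that("trial-wise phase consistency tracks the planted phase relation", {
  # cognitive regime: the signal is antiphase to the alternate state's
  # orientation, so mean z < 0
  sub <- sim_subject(1101, regime = "cognitive", noise_sd = 1)
  cv <- between_state_crossval(sub$bold)
  tw <- trialwise_phase_consistency(sub$bold, phi_alt = cv)
  expect_lt(mean(tw$z, na.rm = TRUE), -0.2)

  # spatial regime: in-phase with the alternate state, mean z > 0
  sub2 <- sim_subject(1102, regime = "spatial", noise_sd = 1)
  cv2 <- between_state_crossval(sub2$bold)
  tw2 <- trialwise_phase_consistency(sub2$bold, phi_alt = cv2)
  expect_gt(mean(tw2$z, na.rm = TRUE), 0.2)

  # pure noise: mean z within Monte-Carlo error of zero
  sub0 <- sim_subject(1103, regime = "none", amplitude = 0, noise_sd = 1)
  tw0 <- trialwise_phase_consistency(sub0$bold,
                                     phi_alt = c(st0 = 10, st90 = 40))
  z0 <- tw0$z[!is.na(tw0$z)]
  expect_lt(abs(mean(z0)), 3 * sd(z0) / sqrt(length(z0)))

  expect_error(
    trialwise_phase_consistency(sub0$bold, phi_alt = c(st0 = 10, st90 = 40),
                                window = 1),
    "window")
})

test_that("trial-wise dynamics regressions recover planted slopes", {
  sub <- sim_subject(1201, regime = "cognitive", noise_sd = 1)
  beh <- sub$behavior
  cv <- between_state_crossval(sub$bold)
  tw <- trialwise_phase_consistency(sub$bold, phi_alt = cv)

  # plant z exactly linear in mini-block with slope -s
  s <- 0.04
  twl <- tw
  twl$z <- 0.5 - s * beh$miniblock
  td <- trialwise_dynamics(twl, beh)
  expect_equal(unname(td$coefs$miniblock["miniblock"]), -s, tolerance = 1e-10)

  # z independent of error: error coefficient near zero at the group level
  cohort_tw <- cohort_bh <- list()
  for (i in 1:6) {
    twz <- tw
    twz$z <- gridshift:::with_seed(1300 + i, rnorm(nrow(tw), 0, 0.1))
    cohort_tw[[i]] <- twz
    cohort_bh[[i]] <- beh
  }
  gd <- trialwise_dynamics(cohort_tw, cohort_bh)
  err_row <- gd$group$error[gd$group$error$term == "logit_err", ]
  expect_gt(err_row$p, 0.05)

  # a collinear covariate shrinks the coefficient of interest toward zero
  tws <- tw
  tws$z <- -0.05 * beh$miniblock +
    gridshift:::with_seed(1400, rnorm(nrow(tw), 0, 0.02))
  td2 <- trialwise_dynamics(tws, beh)
  b_alone <- td2$coefs$miniblock["miniblock"]
  # regress z on logit error with and without the mini-block covariate:
  # since error tracks mini-block, partialling shrinks the error slope
  b_err_alone <- abs(td2$coefs$error["logit_err"])
  b_err_partial <- abs(td2$coefs$error_miniblock["logit_err"])
  expect_lt(b_err_partial, b_err_alone)
  expect_lt(b_alone, 0)
})
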