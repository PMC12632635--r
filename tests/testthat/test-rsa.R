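test_that("single-trial t-maps isolate trial-specific activity", {
  cfg <- task_config(sim_period_choices = 4, iti_period = 12)
  sched <- sim_schedule(1501, n_blocks = 2, n_miniblocks = 2, n_runs = 1,
                        config = cfg)
  beh <- simulate_agent(sched, "transfer_learner", cfg, seed = 1502)
  sim <- bold_sim_config(n_voxels = 20, regime = "none", grid_amplitude = 0,
                         base_amplitude = 0, noise_sd = 0.5, drift_amp = 0.2)
  bold <- simulate_bold(beh, sim, seed = 1503)

  # make voxel 7 respond only during trial 5's simulation period
  j <- 5
  extra <- gridshift:::convolved_regressor(beh$onset_sim[j], beh$sim_dur[j],
                                           5, bold$run_len, bold$TR)
  bold$signal[7, ] <- bold$signal[7, ] + extra

  tp <- single_trial_maps(bold)
  m <- match(j, tp$trials)
  expect_equal(which.max(tp$t[m, ]), 7)
  expect_gt(tp$t[m, 7], 5)
  expect_lt(max(abs(tp$t[-m, 7])), tp$t[m, 7] / 2)
  expect_equal(nrow(tp$t), sum(!beh$missed))
})

test_that("noiseless orthogonal patterns reconstruct the planted similarity", {
  # construct patterns directly: two colors share a pattern family
  set.seed(1601)
  n_tr <- 12; V <- 40
  protos <- matrix(rnorm(3 * V), 3)
  groups <- rep(1:3, each = 4)
  pat <- protos[groups, ] + matrix(rnorm(n_tr * V, 0, 0.05), n_tr)
  D <- neural_rdm(pat)
  expect_true(all(D >= 0 & D <= 2))
  expect_equal(unname(diag(D)), rep(0, n_tr))
  expect_equal(D, t(D))
  same <- outer(groups, groups, `==`) & !diag(n_tr)
  expect_lt(max(D[same]), min(D[!same & !diag(n_tr)]))
})

test_that("hypothesis RDMs encode the intended trial structure", {
  cfg <- task_config()
  sched <- sim_schedule(1701, n_blocks = 2, n_miniblocks = 3, n_runs = 2)
  beh <- simulate_agent(sched, "transfer_learner", cfg, seed = 1702)
  rdms <- build_hypothesis_rdms(beh, cfg, lags = 1:3)

  idm <- rdms$identity
  same_col <- outer(beh$color, beh$color, `==`)
  expect_true(all(idm[same_col] == 0))
  expect_true(all(idm[!same_col] == 1))

  # identical target positions give zero position distance
  pos <- rdms$position
  same_target <- same_col & outer(beh$rotation, beh$rotation, `==`)
  expect_true(all(pos[same_target] < 1e-10))

  # state-invariant position distances ignore the rotation
  inv <- rdms$position_invariant
  expect_true(all(inv[same_col] < 1e-10))

  # lag-1 marks exactly the first off-diagonal within runs
  l1 <- rdms$lag1
  n <- nrow(beh)
  first_off <- cbind(2:n, 1:(n - 1))
  in_run <- beh$run[2:n] == beh$run[1:(n - 1)]
  expect_true(all(l1[first_off[in_run, ]] == 1))
  expect_equal(sum(l1[lower.tri(l1)]), sum(in_run))

  expect_s3_class(as.data.frame(which(rdms$state == 1, arr.ind = TRUE)),
                  "data.frame")
  kinds <- vapply(rdms, attr, character(1), "kind")
  expect_setequal(unique(kinds), c("hypothesis", "covariate"))
})

test_that("RDM regression recovers constructed mixtures and is affine-invariant", {
  cfg <- task_config()
  sched <- sim_schedule(1801, n_blocks = 2, n_miniblocks = 3, n_runs = 2)
  beh <- simulate_agent(sched, "transfer_learner", cfg, seed = 1802)
  rdms <- build_hypothesis_rdms(beh, cfg,
                                which = c("identity", "start_position", "run"))

  # neural RDM equal to one hypothesis: that coefficient 1, others ~ 0
  co <- rdm_regression(rdms$identity, rdms)
  expect_equal(unname(co["identity"]), 1, tolerance = 0.02)
  expect_lt(max(abs(co[c("start_position", "run")])), 0.05)

  # mixtures: coefficients proportional to the planted weights
  lt <- lower.tri(rdms$identity)
  z <- function(m) (m[lt] - mean(m[lt])) / sd(m[lt])
  mix <- matrix(0, nrow(beh), nrow(beh))
  mix[lt] <- 0.8 * z(rdms$identity) + 0.3 * z(rdms$start_position)
  mix <- mix + t(mix)
  co2 <- rdm_regression(mix, rdms[c("identity", "start_position")])
  expect_equal(unname(co2["identity"] / co2["start_position"]), 0.8 / 0.3,
               tolerance = 0.05)

  # affine rescaling of a predictor RDM leaves coefficients unchanged
  rdms_scaled <- rdms
  rdms_scaled$start_position <- 5 * rdms$start_position + 2
  diag(rdms_scaled$start_position) <- 0
  co3 <- rdm_regression(rdms$identity, rdms_scaled)
  expect_equal(co3, co, tolerance = 1e-6)

  # pure-noise neural RDMs give near-zero coefficients on average
  set.seed(1803)
  cos_null <- replicate(60, {
    pat <- matrix(rnorm(nrow(beh) * 30), nrow(beh))
    rdm_regression(neural_rdm(pat), rdms)
  })
  gm <- rowMeans(cos_null)
  se <- apply(cos_null, 1, sd) / sqrt(ncol(cos_null))
  expect_true(all(abs(gm) < 3 * se + 1e-3))

  # collinear predictors are rejected by name
  rdms_bad <- rdms
  rdms_bad$dup <- rdms$identity * 2
  expect_error(rdm_regression(rdms$identity, rdms_bad), "identity ~ dup|dup")
})

test_that("searchlight localizes a planted representational effect", {
  set.seed(1901)
  dims <- c(10, 10, 10); V <- prod(dims)
  n_tr <- 20
  colors <- rep(1:5, 4)
  sphere <- make_spherical_roi(c(4, 4, 4), 6, dims)$index

  pat <- matrix(rnorm(n_tr * V), n_tr)
  protos <- matrix(rnorm(5 * length(sphere), 0, 2), 5)
  pat[, sphere] <- pat[, sphere] + protos[colors, ]

  idm <- structure(outer(colors, colors, `!=`) * 1, kind = "hypothesis")
  sl <- searchlight_rsa(pat, dims, list(identity = idm), radius_mm = 6)
  inside <- mean(sl$maps[sphere, "identity"])
  outside <- mean(sl$maps[-sphere, "identity"], na.rm = TRUE)
  expect_gt(inside, 0.4)
  expect_lt(abs(outside), 0.15)
  expect_gt(inside, outside + 0.3)

  # an interior 9 mm sphere on a 3 mm grid holds 123 voxels
  big <- make_spherical_roi(c(6, 6, 6), 9, c(11, 11, 11))
  expect_equal(length(big$index), 123)

  # averaging a constant coefficient field returns that constant:
  # every sphere of a uniform-effect volume yields the same coefficient
  pat2 <- matrix(rnorm(n_tr * V), n_tr)
  pat2 <- pat2 + protos[colors, rep(1, V)] * 0.5
  sl2 <- searchlight_rsa(pat2, dims, list(identity = idm), radius_mm = 6)
  expect_lt(diff(range(sl2$maps[, "identity"])), 0.5)

  # minimum occupancy: a tight mask skips spheres
  mask <- rep(FALSE, V); mask[sphere[1:5]] <- TRUE
  sl3 <- searchlight_rsa(pat, dims, list(identity = idm), radius_mm = 6,
                         mask = which(mask), min_voxels = 10)
  expect_equal(sort(sl3$skipped), sort(sphere[1:5]))
})

test_that("second-level statistics match the closed-form t-test", {
  set.seed(2001)
  n <- 10; V <- 50
  maps <- matrix(rnorm(n * V, mean = 0.3), n)
  sl <- second_level(maps)
  v <- 17
  expect_equal(sl$t[v], mean(maps[, v]) / (sd(maps[, v]) / sqrt(n)))
  expect_equal(sl$df, n - 1)
  expect_error(second_level(maps[1:2, ]), ">= 3 subjects")

  # an orthogonal covariate has a null slope; a planted slope is detected
  covar <- rnorm(n)
  sl2 <- second_level(maps, covariate = covar)
  expect_lt(mean(abs(sl2$cov_t) > qt(0.975, n - 2)), 0.2)
  maps3 <- maps + outer(covar, rep(0.8, V))
  sl3 <- second_level(maps3, covariate = covar)
  expect_gt(median(sl3$cov_t), median(sl2$cov_t))
  expect_error(second_level(maps, covariate = rnorm(n + 1)), "covariate length")

  # slope t grows with the planted coupling strength
  t_at <- vapply(c(0.2, 0.8, 2), function(cc) {
    median(second_level(maps + outer(covar, rep(cc, V)),
                        covariate = covar)$cov_t)
  }, numeric(1))
  expect_true(all(diff(t_at) > 0))
})

test_that("cluster labeling and sign-flip correction behave as designed", {
  dims <- c(8, 8, 8)
  # all-zero maps: nothing supra-threshold, no clusters
  zero <- matrix(0, 10, prod(dims))
  pc0 <- permutation_cluster_correct(zero + rnorm(length(zero), 0, 1e-12),
                                     dims, n_perm = 100, seed = 1)
  expect_equal(nrow(pc0$clusters), 0)

  # a planted strong 3x3x3 block survives; an isolated weak pair does not
  set.seed(2101)
  n <- 14
  block <- as.vector(outer(outer(2:4, (2:4 - 1) * 8, `+`),
                           (2:4 - 1) * 64, `+`))
  pair <- c(500, 501)
  S <- t(replicate(n, smooth_volume(rnorm(prod(dims)), dims, 2)))
  S[, block] <- S[, block] + 3
  S[, pair] <- S[, pair] + 2.2
  pc <- permutation_cluster_correct(S, dims, n_perm = 300, seed = 2)
  expect_gte(nrow(pc$clusters), 1)
  expect_gte(max(pc$clusters$extent), 20)
  top <- pc$clusters[1, ]
  expect_true(top$peak %in% block)

  # connected-components labeling: face connectivity only
  idx <- c(1, 2, 4, 1 + 8 * 8)      # 1-2 connected; 4 alone; 1+z connected to 1
  comps <- gridshift:::label_clusters(idx, dims)
  sizes <- sort(vapply(comps, length, integer(1)))
  expect_equal(sizes, c(1L, 3L))

  # permutation threshold is stable across seeds (Monte-Carlo error)
  Snull <- null_subject_maps(12, dims, fwhm = 2, seed = 2102)
  k1 <- permutation_cluster_correct(Snull, dims, n_perm = 500, seed = 11)$k
  k2 <- permutation_cluster_correct(Snull, dims, n_perm = 500, seed = 12)$k
  expect_lte(abs(k1 - k2), max(1, 0.2 * max(k1, k2)))
})
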