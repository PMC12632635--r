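test_that("the double-gamma HRF has the canonical shape", {
  dt <- 0.125
  h <- double_gamma_hrf(dt)
  t <- seq(0, 32, by = dt)
  peak <- t[which.max(h)]
  expect_gt(peak, 4); expect_lt(peak, 7)
  expect_equal(max(h), 1)                        # peak-normalized
  expect_lt(min(h), 0)                           # undershoot
  expect_lt(max(abs(h[t > 30])), 1e-3)           # near zero beyond 30 s

  # convolution with a unit impulse returns the kernel
  x <- c(1, rep(0, 400))
  y <- gridshift:::convolve_hrf(x, h)
  expect_equal(y[seq_along(h)], h, tolerance = 1e-10)
})

test_that("OLS betas, t and F statistics match closed-form oracles", {
  set.seed(7)
  n <- 20
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("icpt", "a", "b")
  btrue <- c(0.5, 1, -2)
  y <- X %*% btrue + rnorm(n, sd = 0.3)
  design <- list(X = X)
  fit <- fit_glm(y, design)

  # closed-form beta
  b_hat <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$coef[, 1]), unname(drop(b_hat)), tolerance = 1e-12)

  # hand-computed SE / t for column "a"
  res <- y - X %*% b_hat
  s2 <- sum(res^2) / (n - 3)
  se_a <- sqrt(s2 * solve(crossprod(X))[2, 2])
  expect_equal(unname(gridshift:::glm_t(fit, "a")),
               unname(b_hat[2] / se_a), tolerance = 1e-10)

  # joint F on (a, b) against lm/anova-free brute force
  C <- matrix(0, 2, 3); C[1, 2] <- C[2, 3] <- 1
  bc <- C %*% b_hat
  Fm <- C %*% solve(crossprod(X)) %*% t(C)
  F_oracle <- drop(t(bc) %*% solve(Fm) %*% bc) / (2 * s2)
  ht <- hexagonal_f_test(fit, c("a", "b"))
  expect_equal(unname(ht$F), F_oracle, tolerance = 1e-10)
  expect_equal(unname(ht$Z),
               qnorm(pf(F_oracle, 2, n - 3, lower.tail = FALSE),
                     lower.tail = FALSE), tolerance = 1e-8)
})

test_that("noiseless data from a design are recovered to machine precision and scale linearly", {
  set.seed(8)
  X <- cbind(1, scale(matrix(rnorm(40 * 3), 40)))
  colnames(X) <- c("icpt", paste0("x", 1:3))
  b <- c(2, -1, 0.5, 3)
  y <- drop(X %*% b)
  fit <- fit_glm(y, list(X = X))
  expect_equal(unname(fit$coef[, 1]), b, tolerance = 1e-12)
  fit2 <- fit_glm(3 * y, list(X = X))
  expect_equal(unname(fit2$coef[, 1]), 3 * b, tolerance = 1e-12)
})

test_that("rank-deficient designs fail with the collinear columns named", {
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_glm(rnorm(30), list(X = X)), "null-space")
})

test_that("the F-to-Z transform is monotone, centered and capped", {
  set.seed(9)
  X <- cbind(1, matrix(rnorm(200 * 2), 200))
  colnames(X) <- c("icpt", "a", "b")
  Y <- matrix(rnorm(200 * 200), 200)         # pure noise, many voxels
  fit <- fit_glm(Y, list(X = X))
  ht <- hexagonal_f_test(fit, c("a", "b"))
  # null: mean F near 1, mean Z near 0
  expect_equal(mean(ht$F), 1, tolerance = 0.15)
  expect_lt(abs(mean(ht$Z)), 3 / sqrt(200))
  # monotone in F
  ord <- order(ht$F)
  expect_true(all(diff(ht$Z[ord]) >= 0))
  # F at its own median maps to Z = 0; huge F caps at 37
  Fmed <- qf(0.5, 2, fit$df)
  zmed <- qnorm(pf(Fmed, 2, fit$df, lower.tail = FALSE), lower.tail = FALSE)
  expect_equal(zmed, 0, tolerance = 1e-12)
  ht_forced <- ht; ht_forced$F[1] <- 1e6
  expect_lte(max(ht$Z), 37)
})

test_that("grid design geometry: drift blocks, centering, orthogonality, guards", {
  sub <- sim_subject(301, regime = "spatial", noise_sd = 0.5,
                     n_blocks = 4, n_miniblocks = 6)
  bold <- sub$bold
  ev <- bold$events
  d <- build_grid_design(ev, bold$TR, bold$run_len, k = 6)

  # drift for run 1 is zero over run-2 rows (block diagonality)
  r1_drift <- grep("^run1_drift", colnames(d$X))
  expect_true(all(d$X[d$run_rows[[2]], r1_drift] == 0))
  r2_icpt <- grep("^run2_intercept", colnames(d$X))
  expect_true(all(d$X[d$run_rows[[1]], r2_icpt] == 0))

  # centered quadrature modulators for spread theta are near-orthogonal
  mods <- d$groups$modulators[grepl("^correct", d$groups$modulators)]
  cors <- cor(d$X[, mods])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.25)

  # a modulator column tracks the planted noiseless signal with same phi
  sub0 <- sim_subject(302, regime = "spatial", grid_phi = 0, noise_sd = 0,
                      n_blocks = 4, n_miniblocks = 6)
  b0 <- sub0$bold
  cfg0 <- sub0$sim
  d0 <- build_grid_design(b0$events, b0$TR, b0$run_len, k = 6,
                          modulator = "predicted",
                          phi = c(st0 = 0, st90 = 0))
  y0 <- gridshift:::roi_signal(b0)
  pred_cols <- grep("_pred6$", colnames(d0$X), value = TRUE)
  fitted <- rowSums(d0$X[, pred_cols, drop = FALSE])
  keep <- abs(fitted) > 1e-8
  expect_gt(cor(fitted[keep], y0[keep]), 0.9)

  # constant theta is flagged unidentifiable
  ev_const <- ev
  ev_const$theta <- 12
  d_const <- build_grid_design(ev_const, bold$TR, bold$run_len, k = 6)
  expect_true(length(attr(d_const, "unidentifiable")) > 0)
  expect_error(grid_glm(bold, ev_const), "unidentifiable")

  # theta missing in a modulated condition errors
  ev_na <- ev; ev_na$theta[which(ev_na$correct)[1]] <- NA
  expect_error(build_grid_design(ev_na, bold$TR, bold$run_len),
               "missing theta")
})

test_that("spherical ROIs match brute-force lattice enumeration", {
  count_oracle <- function(radius, vox) {
    m <- ceiling(radius / vox)
    g <- expand.grid(-m:m, -m:m, -m:m)
    sum(vox^2 * rowSums(g^2) <= radius^2)
  }
  dims <- c(21, 21, 21)
  for (r in c(4.5, 9, 10)) {
    roi <- make_spherical_roi(c(11, 11, 11), r, dims)
    expect_equal(length(roi$index), count_oracle(r, 3))
  }
  # the canonical searchlight/ROI sizes on a 3 mm grid
  expect_equal(length(make_spherical_roi(c(11, 11, 11), 9, dims)$index), 123)

  # a radius below the voxel size is just the center voxel
  tiny <- make_spherical_roi(c(5, 5, 5), 2, dims)
  expect_equal(tiny$ijk, matrix(c(5L, 5L, 5L), 1,
                                dimnames = list(NULL, c("i", "j", "k"))),
               ignore_attr = TRUE)

  # edge spheres are clipped; outside centers error
  edge <- make_spherical_roi(c(1, 1, 1), 9, dims)
  expect_lt(length(edge$index), 123)
  expect_error(make_spherical_roi(c(0, 5, 5), 9, dims), "outside")
})
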