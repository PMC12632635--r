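#' Grid orientation from quadrature betas
#'
#' The orientation of a k-fold directional modulation identified from the
#' betas of its sine and cosine regressors:
#' \deqn{\phi = \mathrm{atan2}(\beta_{sin}, \beta_{cos}) / k}
#' reduced to the half-open interval [0, 360/k). The quadrant-aware
#' two-argument arctangent is used (the one-argument ratio form loses the
#' quadrant).
#'
#' @param beta_sin,beta_cos quadrature betas (vectorized).
#' @param k fold symmetry.
#' @return orientation(s) in degrees in [0, 360/k).
#' @export
estimate_grid_angle <- function(beta_sin, beta_cos, k = 6) {
  if (any(beta_sin == 0 & beta_cos == 0)) {
    stop("grid angle unidentifiable: both quadrature betas are zero",
         call. = FALSE)
  }
  wrap_period(rad2deg(atan2(beta_sin, beta_cos)) / k, 360 / k)
}

# reduce to [0, period), treating values within 1e-9 of the period as 0
wrap_period <- function(x, period) {
  r <- x %% period
  r[r > period - 1e-9] <- 0
  r
}

#' Circular distance between two grid angles
#'
#' Minimal distance under the k-fold period 360/k; always in [0, 180/k].
#'
#' @param phi1,phi2 angles in degrees.
#' @param k fold symmetry.
#' @return distance(s) in degrees.
#' @export
angle_difference <- function(phi1, phi2, k = 6) {
  period <- 360 / k
  d <- abs(phi1 - phi2) %% period
  pmin(d, period - d)
}

#' Circular mean of grid angles
#'
#' Angles that live on a 360/k-periodic circle are averaged on unit vectors at
#' k * phi and the resultant divided by k; naive arithmetic averaging is wrong
#' across the wrap.
#'
#' @param phi angles in degrees.
#' @param k fold symmetry.
#' @return mean angle in [0, 360/k).
#' @export
circular_mean_angle <- function(phi, k = 6) {
  a <- deg2rad(k * phi)
  wrap_period(rad2deg(atan2(mean(sin(a)), mean(cos(a)))) / k, 360 / k)
}

#' Fit the k-fold grid-code GLM to an ROI time series
#'
#' The central estimator: fits the quadrature-regressor GLM (see
#' \code{\link{build_grid_design}}) to the mean time series of an ROI and
#' extracts, per condition cell (state, or state x run), the quadrature betas,
#' the grid orientation phi and the modulation amplitude
#' \eqn{\sqrt{\beta_{sin}^2 + \beta_{cos}^2}}.
#'
#' @param bold a \code{bold_dataset}.
#' @param events the event table (defaults to \code{bold$events}).
#' @param k fold symmetry (6 = hexadirectional).
#' @param split_by "state" (runs concatenated; default) or "state_run"
#'   (separate quadrature pairs per state and run).
#' @param roi voxel indices defining the ROI (default: all voxels, averaged).
#' @param nuisance nuisance matrix (defaults to \code{bold$nuisance}).
#' @return an object of class \code{grid_fit}: \code{angles} (data.frame with
#'   state, run, beta_sin, beta_cos, phi, amplitude), \code{k}, \code{fit}
#'   (the underlying \code{glm_fit}) and the call.
#' @export
grid_glm <- function(bold, events = bold$events, k = 6,
                     split_by = c("state", "state_run"), roi = NULL,
                     nuisance = bold$nuisance) {
  split_by <- match.arg(split_by)
  design <- build_grid_design(events, bold$TR, bold$run_len, k = k,
                              split_by = split_by, modulator = "quadrature",
                              nuisance = nuisance)
  bad <- grep("^correct", attr(design, "unidentifiable"), value = TRUE)
  if (length(bad)) {
    stop("grid angle unidentifiable (no angular variance) in cell(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  y <- roi_signal(bold, roi)
  fit <- fit_glm(y, design)

  sin_cols <- grep(paste0("^correct_.*_sin", k, "$"), rownames(fit$coef),
                   value = TRUE)
  angles <- do.call(rbind, lapply(sin_cols, function(sc) {
    cc <- sub(paste0("_sin", k, "$"), paste0("_cos", k), sc)
    cellname <- sub(paste0("^sim_"), "", sub(paste0("_sin", k, "$"), "", sc))
    parts <- strsplit(cellname, "_")[[1]]
    bs <- fit$coef[sc, 1]; bc <- fit$coef[cc, 1]
    data.frame(
      state = parts[2],
      run = if (length(parts) >= 3) as.integer(sub("^r", "", parts[3])) else NA_integer_,
      beta_sin = bs, beta_cos = bc,
      phi = estimate_grid_angle(bs, bc, k),
      amplitude = sqrt(bs^2 + bc^2)
    )
  }))
  rownames(angles) <- NULL
  structure(list(angles = angles, k = k, fit = fit, split_by = split_by,
                 call = match.call()),
            class = "grid_fit")
}

#' @export
print.grid_fit <- function(x, ...) {
  cat("<grid_fit> k =", x$k, "fold grid-code GLM (split:", x$split_by, ")\n")
  print(transform(x$angles, phi = round(phi, 2),
                  beta_sin = signif(beta_sin, 3),
                  beta_cos = signif(beta_cos, 3),
                  amplitude = signif(amplitude, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.grid_fit <- function(object, ...) {
  m <- as.matrix(object$angles[, c("beta_sin", "beta_cos")])
  rownames(m) <- paste0(object$angles$state,
                        ifelse(is.na(object$angles$run), "",
                               paste0("_r", object$angles$run)))
  m
}

#' @export
summary.grid_fit <- function(object, ...) {
  ht <- hexagonal_f_test(object$fit)
  structure(list(angles = object$angles, k = object$k, hex = ht),
            class = "summary.grid_fit")
}

#' @export
print.summary.grid_fit <- function(x, ...) {
  cat("k =", x$k, "fold grid-code fit\n")
  print(transform(x$angles, phi = round(phi, 2)), row.names = FALSE)
  cat("joint modulation F(", x$hex$df1, ",", x$hex$df2, ") = ",
      signif(x$hex$F[1], 4), ",  Z = ", round(x$hex$Z[1], 2), "\n", sep = "")
  invisible(x)
}

#' Predicted k-fold modulation profile
#'
#' Evaluates \code{amplitude * cos(k[theta - phi])} for a fitted state.
#'
#' @param object a \code{grid_fit}.
#' @param theta angles of travel (degrees) at which to predict.
#' @param state state label (defaults to the first fitted state).
#' @param ... unused.
#' @return numeric vector of predicted modulation values.
#' @export
predict.grid_fit <- function(object, theta, state = object$angles$state[1], ...) {
  row <- object$angles[object$angles$state == state, ][1, ]
  row$amplitude * cos(deg2rad(object$k * (theta - row$phi)))
}

#' @export
plot.grid_fit <- function(x, state = x$angles$state[1], ...) {
  th <- seq(0, 360, length.out = 361)
  graphics::plot(th, predict(x, th, state = state), type = "l",
                 xlab = expression(theta ~ "(deg)"),
                 ylab = "predicted modulation",
                 main = paste0(x$k, "-fold modulation, state ", state), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
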