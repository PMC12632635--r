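#' Fit a massively univariate OLS GLM
#'
#' Ordinary least squares of every voxel's time series on a design matrix.
#' Rank deficiency is an error that names the columns in the null space.
#'
#' @param bold a \code{bold_dataset}, a time x voxel matrix, or a numeric
#'   vector (single time series).
#' @param design a \code{grid_design} (or any list with an \code{X} matrix).
#' @return an object of class \code{glm_fit}: \code{coef} (p x V),
#'   \code{sigma2} (residual variance per voxel), \code{df} (error degrees of
#'   freedom, rows - rank), \code{XtX_inv}, \code{residuals} (time x V) and
#'   the design.
#' @export
fit_glm <- function(bold, design) {
  Y <- if (inherits(bold, "bold_dataset")) t(bold$signal)
  else if (is.null(dim(bold))) matrix(bold, ncol = 1)
  else as.matrix(bold)
  X <- design$X
  if (nrow(Y) != nrow(X)) {
    stop("time dimension mismatch: ", nrow(Y), " scans vs ", nrow(X),
         " design rows", call. = FALSE)
  }
  qrX <- qr(X)
  p <- ncol(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; null-space column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, Y)
  rownames(beta) <- colnames(X)
  res <- Y - X %*% beta
  df <- nrow(X) - p
  sigma2 <- colSums(res^2) / df
  A <- chol2inv(qr.R(qrX))          # ((X[,pivot])' X[,pivot])^{-1}
  ip <- order(qrX$pivot)
  XtX_inv <- A[ip, ip, drop = FALSE]
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  structure(list(coef = beta, sigma2 = sigma2, df = df,
                 XtX_inv = XtX_inv, residuals = res, design = design),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit>", nrow(x$coef), "coefficients x", ncol(x$coef),
      "voxel(s); error df", x$df, "\n")
  invisible(x)
}

#' @export
coef.glm_fit <- function(object, ...) object$coef

# t statistic for one design column, per voxel.
glm_t <- function(fit, column) {
  j <- match(column, rownames(fit$coef))
  if (is.na(j)) stop("no design column named '", column, "'", call. = FALSE)
  se <- sqrt(fit$XtX_inv[j, j] * fit$sigma2)
  fit$coef[j, ] / se
}

#' Joint F-test on modulator betas with F-to-Z transform
#'
#' Tests the joint null that a set of parametric-modulator betas (by default
#' the sin/cos quadrature pairs of the correct-response conditions in every
#' state) are all zero, voxelwise. The F statistic is mapped to a Z statistic
#' through the p-value route, Z = qnorm(1 - p(F)), computed in log space so
#' that large F values stay finite; |Z| is capped at 37 (the limit of double
#' precision for the normal quantile).
#'
#' @param fit a \code{glm_fit}.
#' @param modulator_names design columns to test jointly; default: all
#'   quadrature modulators of correct conditions.
#' @return an object of class \code{hex_test}: \code{F}, \code{Z} (per voxel),
#'   \code{df1}, \code{df2}, \code{columns}.
#' @export
hexagonal_f_test <- function(fit, modulator_names = NULL) {
  if (is.null(modulator_names)) {
    mods <- fit$design$groups$modulators
    modulator_names <- grep("^correct_", mods, value = TRUE)
    if (length(modulator_names) == 0) modulator_names <- mods
  }
  idx <- match(modulator_names, rownames(fit$coef))
  if (anyNA(idx)) {
    stop("missing design column(s): ",
         paste(modulator_names[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  q <- length(idx)
  B <- fit$coef[idx, , drop = FALSE]                     # q x V
  M <- fit$XtX_inv[idx, idx, drop = FALSE]
  W <- solve(M, B)
  Fstat <- colSums(B * W) / (q * fit$sigma2)
  logp <- stats::pf(Fstat, q, fit$df, lower.tail = FALSE, log.p = TRUE)
  Z <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  Z <- pmin(pmax(Z, -37), 37)
  structure(list(F = Fstat, Z = Z, df1 = q, df2 = fit$df,
                 columns = modulator_names),
            class = "hex_test")
}

#' @export
print.hex_test <- function(x, ...) {
  cat("<hex_test> F(", x$df1, ",", x$df2, ") over ",
      length(x$F), " voxel(s); median Z = ",
      round(stats::median(x$Z), 2), "\n", sep = "")
  invisible(x)
}

#' Spherical region of interest on a voxel grid
#'
#' All voxels whose centers lie within \code{radius_mm} of the center voxel's
#' center (the center voxel is always included). Spheres near the grid edge
#' are clipped to in-grid voxels.
#'
#' @param center_voxel integer (i, j, k) index, 1-based.
#' @param radius_mm sphere radius in mm (> 0).
#' @param dims grid dimensions.
#' @param voxel_size voxel edge length in mm (default 3, isotropic).
#' @return list with \code{index} (linear voxel indices), \code{ijk} (matrix
#'   of coordinates) and \code{offsets} (the unclipped integer offset set).
#' @export
make_spherical_roi <- function(center_voxel, radius_mm, dims, voxel_size = 3) {
  stopifnot(radius_mm > 0, length(center_voxel) == 3, length(dims) == 3)
  center_voxel <- as.integer(center_voxel)
  if (any(center_voxel < 1) || any(center_voxel > dims)) {
    stop("center voxel ", paste(center_voxel, collapse = ","),
         " is outside the grid", call. = FALSE)
  }
  offsets <- sphere_offsets(radius_mm, voxel_size)
  ijk <- sweep(offsets, 2, center_voxel, `+`)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  ijk <- ijk[ok, , drop = FALSE]
  index <- ijk[, 1] + (ijk[, 2] - 1) * dims[1] + (ijk[, 3] - 1) * dims[1] * dims[2]
  list(index = as.integer(index), ijk = ijk, offsets = offsets)
}

# Integer offsets (i,j,k) with || voxel_size * (i,j,k) || <= radius_mm.
sphere_offsets <- function(radius_mm, voxel_size) {
  m <- floor(radius_mm / voxel_size)
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  keep <- voxel_size^2 * (g$i^2 + g$j^2 + g$k^2) <= radius_mm^2
  as.matrix(g[keep, , drop = FALSE])
}
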