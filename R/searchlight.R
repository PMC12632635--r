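#' Searchlight RDM regression
#'
#' Moves a spherical searchlight (default 9 mm radius on a 3 mm grid, 123
#' voxels in the interior) across every in-mask voxel, computes the neural
#' RDM (1 - Pearson r) over the sphere's voxels, regresses the model RDMs on
#' it, and assigns each voxel the average coefficient over all spheres that
#' contained it. Spheres with fewer than \code{min_voxels} in-mask voxels are
#' skipped and recorded.
#'
#' @param patterns a \code{trial_patterns} (trial x voxel, voxels in grid
#'   order) or plain matrix.
#' @param dims 3D grid dimensions (prod(dims) = number of voxels).
#' @param hypothesis_set named list of model RDMs.
#' @param radius_mm searchlight radius (default 9).
#' @param voxel_size voxel edge in mm (default 3).
#' @param mask logical/index vector of voxels to use (default all).
#' @param min_voxels minimum sphere occupancy (default 10).
#' @return an object of class \code{searchlight_maps}: \code{maps} (voxel x
#'   predictor coefficient matrix, NA outside coverage), \code{counts}
#'   (spheres contributing per voxel), \code{skipped} (centers skipped).
#' @export
searchlight_rsa <- function(patterns, dims, hypothesis_set,
                            radius_mm = 9, voxel_size = 3,
                            mask = NULL, min_voxels = 10) {
  M <- if (inherits(patterns, "trial_patterns")) patterns$t else as.matrix(patterns)
  n_vox <- prod(dims)
  stopifnot(ncol(M) == n_vox)
  in_mask <- rep(FALSE, n_vox)
  if (is.null(mask)) in_mask[] <- TRUE else in_mask[mask] <- TRUE

  n_tr <- nrow(M)
  lt <- lower.tri(matrix(0, n_tr, n_tr))
  P <- vapply(names(hypothesis_set),
              function(nm) zscore(hypothesis_set[[nm]][lt], nm),
              numeric(sum(lt)))
  X <- cbind(1, P)
  qrX <- qr(X)

  offsets <- sphere_offsets(radius_mm, voxel_size)
  centers <- which(in_mask)
  cijk <- arrayInd(centers, dims)

  acc <- matrix(0, n_vox, length(hypothesis_set))
  counts <- integer(n_vox)
  skipped <- integer(0)
  for (ci in seq_along(centers)) {
    ijk <- sweep(offsets, 2, cijk[ci, ], `+`)
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
    vox <- ijk[ok, 1] + (ijk[ok, 2] - 1) * dims[1] +
      (ijk[ok, 3] - 1) * dims[1] * dims[2]
    vox <- vox[in_mask[vox]]
    if (length(vox) < min_voxels) {
      skipped <- c(skipped, centers[ci])
      next
    }
    D <- 1 - stats::cor(t(M[, vox, drop = FALSE]))
    yv <- D[lt]
    s <- stats::sd(yv)
    if (!is.finite(s) || s == 0) { skipped <- c(skipped, centers[ci]); next }
    beta <- qr.coef(qrX, (yv - mean(yv)) / s)[-1]
    acc[vox, ] <- acc[vox, , drop = FALSE] + rep(beta, each = length(vox))
    counts[vox] <- counts[vox] + 1L
  }
  maps <- acc / counts
  maps[counts == 0, ] <- NA_real_
  colnames(maps) <- names(hypothesis_set)
  structure(list(maps = maps, counts = counts, skipped = skipped,
                 dims = dims, radius_mm = radius_mm),
            class = "searchlight_maps")
}

#' @export
print.searchlight_maps <- function(x, ...) {
  cat("<searchlight_maps>", sum(x$counts > 0), "covered voxels,",
      ncol(x$maps), "predictor(s); radius", x$radius_mm, "mm;",
      length(x$skipped), "center(s) skipped\n")
  invisible(x)
}

#' Second-level tests on subject coefficient maps
#'
#' Per-voxel one-sample t-test of subject maps against zero and, when a
#' behavioral covariate is supplied, the per-voxel slope t-statistic from OLS
#' of the maps on the centered covariate. The covariate test is typically
#' restricted to a mask of voxels already showing a group effect.
#'
#' @param maps subject x voxel matrix (or list of per-subject vectors).
#' @param covariate optional per-subject behavioral measure (centered
#'   internally; logit-transform error measures beforehand).
#' @param mask optional voxel subset (logical or indices); voxels outside get
#'   NA.
#' @return an object of class \code{second_level}: \code{t} (intercept t per
#'   voxel), \code{df}, and with a covariate \code{cov_t}, \code{cov_df}.
#' @export
second_level <- function(maps, covariate = NULL, mask = NULL) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  n <- nrow(maps); V <- ncol(maps)
  if (n < 3) stop("second-level tests need >= 3 subjects", call. = FALSE)
  use <- rep(TRUE, V)
  if (!is.null(mask)) { use <- rep(FALSE, V); use[mask] <- TRUE }

  mu <- colMeans(maps)
  sdv <- sqrt(colSums(sweep(maps, 2, mu)^2) / (n - 1))
  tmap <- ifelse(use, mu / (sdv / sqrt(n)), NA_real_)
  out <- list(t = tmap, df = n - 1, n = n)

  if (!is.null(covariate)) {
    if (length(covariate) != n) {
      stop("covariate length ", length(covariate), " does not match ",
           n, " subjects", call. = FALSE)
    }
    x <- covariate - mean(covariate)
    sxx <- sum(x^2)
    slope <- drop(crossprod(x, maps)) / sxx
    fitted <- outer(rep(1, n), mu) + outer(x, slope)
    rss <- colSums((maps - fitted)^2)
    se <- sqrt(rss / (n - 2) / sxx)
    out$cov_t <- ifelse(use, slope / se, NA_real_)
    out$cov_df <- n - 2
  }
  structure(out, class = "second_level")
}

#' @export
print.second_level <- function(x, ...) {
  cat("<second_level>", length(x$t), "voxels, n =", x$n,
      "; max |t| =", round(max(abs(x$t), na.rm = TRUE), 2), "\n")
  invisible(x)
}

# Label connected components (face/6-neighbor connectivity) among `idx`
# voxels of a dims grid. Returns a list of integer vectors (voxel indices).
label_clusters <- function(idx, dims) {
  if (length(idx) == 0) return(list())
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  member <- new.env(hash = TRUE, size = length(idx) * 2)
  for (v in idx) assign(as.character(v), TRUE, envir = member)
  seen <- new.env(hash = TRUE, size = length(idx) * 2)
  ijk <- arrayInd(idx, dims)
  rownames(ijk) <- as.character(idx)
  clusters <- list()
  for (v in idx) {
    key <- as.character(v)
    if (exists(key, envir = seen, inherits = FALSE)) next
    comp <- integer(0)
    queue <- v
    assign(key, TRUE, envir = seen)
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, u)
      uc <- arrayInd(u, dims)[1, ]
      nb <- c(if (uc[1] > 1) u - 1L, if (uc[1] < dims[1]) u + 1L,
              if (uc[2] > 1) u - nx, if (uc[2] < dims[2]) u + nx,
              if (uc[3] > 1) u - nxy, if (uc[3] < dims[3]) u + nxy)
      for (w in nb) {
        kw <- as.character(w)
        if (exists(kw, envir = member, inherits = FALSE) &&
            !exists(kw, envir = seen, inherits = FALSE)) {
          assign(kw, TRUE, envir = seen)
          queue <- c(queue, w)
        }
      }
    }
    clusters[[length(clusters) + 1]] <- comp
  }
  clusters
}

# max cluster extent over both tails for a t map
max_cluster_extent <- function(tmap, thr, dims) {
  m <- 0L
  for (sgn in c(1, -1)) {
    supra <- which(sgn * tmap > thr)
    if (length(supra)) {
      m <- max(m, max(vapply(label_clusters(supra, dims), length, integer(1))))
    }
  }
  m
}

#' Sign-flip cluster-extent permutation correction
#'
#' Family-wise error control for second-level t maps. Observed clusters are
#' connected components (6-neighbor connectivity) of voxels exceeding the
#' cluster-forming threshold (two-tailed p < 0.001 by default, positive and
#' negative tails thresholded separately). The null is built by repeatedly
#' flipping the sign of a random half of the subjects' maps (exactly
#' floor(n/2) subjects per permutation by default, or independent fair coins
#' with \code{flip = "coin"}), recomputing the t map and recording the
#' maximum cluster extent over both tails. A cluster survives when its
#' corrected p-value, (1 + count of null maxima at or above its extent) /
#' (n_perm + 1), is at most 0.05; the reported extent threshold k is the
#' smallest surviving extent - the exact 95th-percentile cut of the discrete
#' null, which keeps the family-wise error at the nominal rate in the
#' presence of ties.
#'
#' @param subject_maps subject x voxel matrix.
#' @param dims 3D grid dimensions.
#' @param mask optional in-mask voxel indices/logical.
#' @param p_cluster_form two-tailed cluster-forming p (default 0.001).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the flip draws.
#' @param flip "half" (default) or "coin".
#' @return an object of class \code{cluster_perm}: \code{k} (extent
#'   threshold), \code{clusters} (data.frame: id, sign, extent, peak voxel
#'   index, peak t), \code{threshold_t}, \code{null_max}, \code{t} (observed
#'   map).
#' @export
permutation_cluster_correct <- function(subject_maps, dims, mask = NULL,
                                        p_cluster_form = 0.001,
                                        n_perm = 1000, seed = NULL,
                                        flip = c("half", "coin")) {
  flip <- match.arg(flip)
  stopifnot(n_perm >= 100)
  S <- as.matrix(subject_maps)
  n <- nrow(S); V <- ncol(S)
  stopifnot(V == prod(dims))
  use <- rep(TRUE, V)
  if (!is.null(mask)) { use <- rep(FALSE, V); use[mask] <- TRUE }
  if (!any(use)) stop("no in-mask voxels", call. = FALSE)
  S[, !use] <- 0

  df <- n - 1
  thr <- stats::qt(1 - p_cluster_form / 2, df)
  ss <- colSums(S^2)

  t_of_means <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    v[v <= 0] <- Inf
    m / sqrt(v / n)
  }
  t_obs <- t_of_means(colMeans(S))
  t_obs[!use] <- 0

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      f <- rep(1, n)
      if (flip == "half") {
        f[sample.int(n, floor(n / 2))] <- -1
      } else {
        f <- sample(c(-1, 1), n, replace = TRUE)
      }
      tm <- t_of_means(drop(crossprod(f, S)) / n)
      tm[!use] <- 0
      max_cluster_extent(tm, thr, dims)
    }, numeric(1))
  })
  # smallest extent whose corrected p = (1 + #{null >= k}) / (n_perm + 1)
  # is <= 0.05: the exact tie-aware 95th-percentile cut of the discrete null
  cand <- sort(unique(c(null_max, max(null_max) + 1)))
  pcorr <- vapply(cand, function(kk) (1 + sum(null_max >= kk)) / (n_perm + 1),
                  numeric(1))
  ok <- which(pcorr <= 0.05)
  k <- if (length(ok)) cand[ok[1]] else Inf

  rows <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * t_obs > thr)
    if (!length(supra)) next
    for (cl in label_clusters(supra, dims)) {
      if (length(cl) >= k) {
        pk <- cl[which.max(abs(t_obs[cl]))]
        rows[[length(rows) + 1]] <- data.frame(
          sign = sgn, extent = length(cl), peak = pk, peak_t = t_obs[pk],
          p_corrected = (1 + sum(null_max >= length(cl))) / (n_perm + 1))
      }
    }
  }
  clusters <- if (length(rows)) {
    out <- do.call(rbind, rows)
    out <- out[order(-out$extent), , drop = FALSE]
    out$id <- seq_len(nrow(out))
    out[, c("id", "sign", "extent", "peak", "peak_t", "p_corrected")]
  } else {
    data.frame(id = integer(0), sign = numeric(0), extent = integer(0),
               peak = integer(0), peak_t = numeric(0),
               p_corrected = numeric(0))
  }
  structure(list(k = k, clusters = clusters, threshold_t = thr,
                 null_max = null_max, t = t_obs, df = df, dims = dims),
            class = "cluster_perm")
}

#' @export
print.cluster_perm <- function(x, ...) {
  cat("<cluster_perm> cluster-forming |t| >", round(x$threshold_t, 2),
      "(df", x$df, "); extent threshold k =", round(x$k, 1), "\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE, digits = 3)
  else cat("  no surviving clusters\n")
  invisible(x)
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Utility for building spatially smooth simulated subject maps (cluster
#' statistics are only meaningful on smooth fields). FWHM is in voxels.
#'
#' @param vol numeric vector (length prod(dims)) or 3D array.
#' @param dims grid dimensions.
#' @param fwhm_vox full width at half maximum of the Gaussian, in voxels.
#' @return smoothed volume as a vector of length prod(dims).
#' @export
smooth_volume <- function(vol, dims, fwhm_vox = 2) {
  a <- array(vol, dim = dims)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  smooth_axis <- function(mat) {
    # smooth each column of mat with the kernel (replicate-pad ends)
    n <- nrow(mat)
    pad <- rbind(mat[rep(1, half), , drop = FALSE], mat,
                 mat[rep(n, half), , drop = FALSE])
    out <- matrix(0, n, ncol(mat))
    for (s in seq_along(kern)) {
      out <- out + kern[s] * pad[(s - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  # axis 1
  a <- array(smooth_axis(matrix(a, dims[1], dims[2] * dims[3])), dims)
  # axis 2
  a <- aperm(a, c(2, 1, 3))
  a <- array(smooth_axis(matrix(a, dims[2], dims[1] * dims[3])),
             dims[c(2, 1, 3)])
  a <- aperm(a, c(2, 1, 3))
  # axis 3
  a <- aperm(a, c(3, 1, 2))
  a <- array(smooth_axis(matrix(a, dims[3], dims[1] * dims[2])),
             dims[c(3, 1, 2)])
  a <- aperm(a, c(2, 3, 1))
  as.numeric(a)
}
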