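#' @keywords internal
#' @import stats
#' @import utils
"_PACKAGE"

# Angle helpers. Public convention throughout the package: screen origin at the
# arena center, 0 degrees along the positive x-axis, counterclockwise positive,
# all angles in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into [0, 360)
#' @param x angle(s) in degrees
#' @return angle(s) in [0, 360)
#' @export
wrap_angle <- function(x) x %% 360

#' Minimal angular distance between two angles
#'
#' The absolute circular distance, in degrees, between two polar angles;
#' always in [0, 180].
#'
#' @param a,b angles in degrees
#' @return distance(s) in [0, 180]
#' @export
angular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Polar angle (degrees in [0,360)) of points about a center.
point_angle <- function(x, y, center = c(0, 0)) {
  wrap_angle(rad2deg(atan2(y - center[2], x - center[1])))
}

# Euclidean norm rowwise for 2-column matrices / paired vectors.
euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL leaves the current stream in place.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive n reproducible child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n, labels = NULL) {
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(labels)) names(s) <- labels
  s
}

# z-score a vector; error on zero variance unless allow_constant.
zscore <- function(x, label = "vector") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score '", label, "': zero or undefined variance", call. = FALSE)
  }
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
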