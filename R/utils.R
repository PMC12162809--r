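## Small numerical helpers shared across modules.
## Unit system: mm, s, kPa (force unit mN = kPa * mm^2).

#' Evaluate a point on a cubic Bezier curve
#'
#' Cubic Bernstein interpolation of four planar (or n-dimensional) control
#' points. Endpoint interpolation holds exactly: `t = 0` returns the first
#' control point and `t = 1` the last.
#'
#' @param control_points numeric matrix with 4 rows (control points) and one
#'   column per coordinate.
#' @param t curve parameter(s) in `[0, 1]`; may be a vector.
#' @return matrix with `length(t)` rows of curve points.
#' @export
bezier_point <- function(control_points, t) {
  cp <- as.matrix(control_points)
  if (nrow(cp) != 4L) stop("cubic Bezier needs exactly 4 control points")
  if (any(t < 0 | t > 1)) stop("Bezier parameter t must lie in [0, 1]")
  b0 <- (1 - t)^3
  b1 <- 3 * t * (1 - t)^2
  b2 <- 3 * t^2 * (1 - t)
  b3 <- t^3
  cbind(b0, b1, b2, b3) %*% cp
}

## quadratic Bezier (used for the guided belly curve and fillet blends)
bezier2_point <- function(control_points, t) {
  cp <- as.matrix(control_points)
  if (nrow(cp) != 3L) stop("quadratic Bezier needs exactly 3 control points")
  cbind((1 - t)^2, 2 * t * (1 - t), t^2) %*% cp
}

## cumulative chord length of a polyline (rows = points)
polyline_length <- function(pts) {
  d <- diff(pts)
  sum(sqrt(rowSums(d * d)))
}

## resample a parametric curve at parameters giving (approximately) uniform
## arc length; fn(t) must return a matrix of points for a vector t
arc_uniform_params <- function(fn, n, oversample = 40L) {
  tt <- seq(0, 1, length.out = n * oversample + 1L)
  pts <- fn(tt)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  s <- s / s[length(s)]
  stats::approx(s, tt, xout = seq(0, 1, length.out = n), ties = "ordered")$y
}

#' Arc length of a sampled curve by piecewise-quadratic integration
#'
#' Fits local quadratics through consecutive point triplets and integrates
#' their speed with Gauss--Legendre quadrature, giving second-order accurate
#' arc lengths on smooth curves (each refinement at least halves the error on
#' a circular arc).
#'
#' @param pts matrix of curve points (rows ordered along the curve).
#' @return arc length (same units as the coordinates).
#' @export
arc_length_quadratic <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2L) return(0)
  if (n == 2L) return(sqrt(sum((pts[2L, ] - pts[1L, ])^2)))
  ## 3-point Gauss rule on [0,1]
  gp <- c(0.5 - sqrt(15) / 10, 0.5, 0.5 + sqrt(15) / 10)
  gw <- c(5, 8, 5) / 18
  total <- 0
  for (k in seq_len(n - 1L)) {
    ## local quadratic through points k-1,k,k+1 (shifted at the ends),
    ## integrated over the segment [k, k+1]
    i0 <- max(1L, min(k, n - 2L))
    p0 <- pts[i0, ]; p1 <- pts[i0 + 1L, ]; p2 <- pts[i0 + 2L, ]
    ## parameterize u in {0,1,2} at the three points; segment is
    ## [k - i0, k - i0 + 1] in u
    a <- (p0 - 2 * p1 + p2) / 2
    b <- (p2 - p0) / 2
    u0 <- k - i0
    for (g in seq_along(gp)) {
      u <- u0 + gp[g]
      du <- 2 * a * (u - 1) + b  ## derivative of p(u) = p1 + b(u-1) + a(u-1)^2
      total <- total + gw[g] * sqrt(sum(du * du))
    }
  }
  total
}

## rotation matrix about the x-axis
rot_x <- function(a) {
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

## rotation about the z (valve) axis
rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

## random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## 3x3 determinant, unrolled (fast path used in assembly loops)
det3 <- function(m) {
  m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
    m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
    m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
}

## vectorized determinants for an n x 3 x 3 array
det3_arr <- function(a) {
  a[, 1, 1] * (a[, 2, 2] * a[, 3, 3] - a[, 2, 3] * a[, 3, 2]) -
    a[, 1, 2] * (a[, 2, 1] * a[, 3, 3] - a[, 2, 3] * a[, 3, 1]) +
    a[, 1, 3] * (a[, 2, 1] * a[, 3, 2] - a[, 2, 2] * a[, 3, 1])
}

## vectorized 3x3 matrix product for n x 3 x 3 arrays: C = A %*% B per slice
matmul3_arr <- function(a, b) {
  out <- array(0, dim(a))
  for (i in 1:3) for (j in 1:3) {
    out[, i, j] <- a[, i, 1] * b[, 1, j] + a[, i, 2] * b[, 2, j] +
      a[, i, 3] * b[, 3, j]
  }
  out
}

## vectorized transpose for n x 3 x 3 arrays
t3_arr <- function(a) aperm(a, c(1, 3, 2))

## von Mises equivalent stress from a symmetric 3x3 stress (or n x 3 x 3 array)
von_mises <- function(sig) {
  if (is.matrix(sig)) sig <- array(sig, c(1, 3, 3))
  s11 <- sig[, 1, 1]; s22 <- sig[, 2, 2]; s33 <- sig[, 3, 3]
  s12 <- sig[, 1, 2]; s13 <- sig[, 1, 3]; s23 <- sig[, 2, 3]
  sqrt(0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) +
         3 * (s12^2 + s13^2 + s23^2))
}

## normalize rows of a matrix
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m * m))
  m / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
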