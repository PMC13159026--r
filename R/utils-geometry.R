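# Small 2D/3D geometry helpers shared across modules.

#' Signed polygon area (shoelace formula)
#'
#' @param pts n x 2 matrix of polygon vertices (closed implicitly).
#' @return Signed area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polyline length
#'
#' @param pts n x 2 (or n x 3) matrix of consecutive points.
#' @param closed If TRUE, include the closing segment.
#' @return Total length.
#' @export
polyline_length <- function(pts, closed = FALSE) {
  if (nrow(pts) < 2) return(0)
  d <- diff(pts)
  len <- sum(sqrt(rowSums(d^2)))
  if (closed) len <- len + sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  len
}

# cumulative arc length along a polyline, starting at 0
cum_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps^0.5) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# apply a 4x4 homogeneous transform to an n x 3 matrix of points
apply_rigid <- function(transform, pts) {
  pts <- rbind(pts)  # tolerate single point vectors
  if (is.null(dim(pts)) || ncol(pts) != 3) pts <- matrix(pts, ncol = 3)
  out <- cbind(pts, 1) %*% t(transform)
  out[, 1:3, drop = FALSE]
}

# linear interpolation of f at position x given sorted xs
interp1 <- function(xs, fs, x) {
  stats::approx(xs, fs, xout = x, rule = 2, ties = list("ordered", mean))$y
}
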