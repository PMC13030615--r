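# Conventions used throughout the package (stated once, used everywhere):
#   world frame: x downhill, y across the slope, z up, units metres;
#   image frame: origin top-left, x right, y down, units pixels.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix aiming a camera at a target
#'
#' Builds a proper world-to-camera rotation whose third row (the optical
#' axis) points from `position` toward `target`, with the image y axis
#' pointing down in the world (z-up) sense.
#'
#' @param position camera centre, metres (length 3).
#' @param target point the camera looks at, metres (length 3).
#' @return 3x3 rotation matrix with rows (right, down, forward).
#' @keywords internal
look_at_rotation <- function(position, target) {
  fwd <- unit3(target - position)
  if (abs(fwd[3]) > 1 - 1e-9) stop("camera looking straight up/down is degenerate")
  right <- unit3(cross3(fwd, c(0, 0, 1)))
  down <- cross3(fwd, right)
  rbind(right, down, fwd, deparse.level = 0)
}

#' Assemble a 3x4 projection matrix
#'
#' Ideal pinhole model (no lens distortion): P = K [R | -R c] with square
#' pixels and a single focal length in pixels.
#'
#' @param focal_px focal length in pixels.
#' @param principal_point image centre, pixels (length 2).
#' @param rotation 3x3 world-to-camera rotation.
#' @param position camera centre in world coordinates, metres.
#' @return 3x4 numeric matrix.
#' @export
camera_matrix <- function(focal_px, principal_point, rotation, position) {
  K <- matrix(c(focal_px, 0, principal_point[1],
                0, focal_px, principal_point[2],
                0, 0, 1), nrow = 3, byrow = TRUE)
  K %*% cbind(rotation, -rotation %*% position)
}

#' Project world points through a projection matrix
#'
#' @param P 3x4 projection matrix.
#' @param X n x 3 matrix (or length-3 vector) of world points, metres.
#' @return n x 3 matrix with columns u, v (pixels) and depth (the third
#'   homogeneous coordinate before dehomogenization; positive in front of
#'   the camera when P is scaled with positive-depth convention).
#' @export
project_points <- function(P, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xh <- cbind(X, 1)
  ph <- Xh %*% t(P)
  cbind(u = ph[, 1] / ph[, 3], v = ph[, 2] / ph[, 3], depth = ph[, 3])
}
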