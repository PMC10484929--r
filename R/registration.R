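# Two-landmark rigid alignment. Each brain carries a line drawn between two
# recognizable landmarks; the line's in-plane direction fixes the rotation
# about z, its in-plane length the isotropic scale, and its first endpoint
# the translation. Brains are assumed flat-landed: no tilt about x or y.

#' Construct a landmark line
#'
#' @param p0,p1 numeric triples (y, x, z), 0-based voxel coordinates.
#' @return object of class `landmark_line`.
#' @export
landmark_line <- function(p0, p1) {
  p0 <- as_triple(p0, "p0"); p1 <- as_triple(p1, "p1")
  assert_that(any(p0 != p1), "landmark endpoints must differ")
  d <- p1 - p0
  assert_that(sqrt(sum(d[1:2]^2)) > 0,
              "landmark line must have a nonzero in-plane (y, x) component")
  structure(list(p0 = p0, p1 = p1), class = "landmark_line")
}

#' Construct an in-plane rigid + isotropic-scale pose
#'
#' The pose maps a point p = (y, x, z) to `scale * Rz(theta) p + translation`,
#' where Rz rotates the (y, x) components about the z axis. When
#' `scale_z = TRUE` (default) the same scale factor is applied to z; z is
#' never rotated or tilted.
#'
#' @param theta_rad rotation angle about z (radians).
#' @param scale positive isotropic scale factor.
#' @param translation numeric triple (y, x, z).
#' @param scale_z logical; stretch z by the same factor as the plane.
#' @return object of class `pose_z`.
#' @export
pose_z <- function(theta_rad = 0, scale = 1, translation = c(0, 0, 0),
                   scale_z = TRUE) {
  assert_that(is.numeric(scale) && scale > 0, "scale must be positive")
  structure(list(theta_rad = as.numeric(theta_rad), scale = as.numeric(scale),
                 translation = as_triple(translation, "translation"),
                 scale_z = isTRUE(scale_z)),
            class = "pose_z")
}

#' @export
print.pose_z <- function(x, ...) {
  cat(sprintf("<pose_z> theta = %.6g rad, scale = %.6g%s, t = (%s)\n",
              x$theta_rad, x$scale, if (x$scale_z) " (incl. z)" else " (xy only)",
              paste(signif(x$translation, 6), collapse = ", ")))
  invisible(x)
}

# In-plane angle of the (y, x) displacement, measured as atan2(dy, dx).
line_angle <- function(line) {
  d <- line$p1 - line$p0
  atan2(d[1], d[2])
}

line_inplane_length <- function(line) {
  d <- line$p1 - line$p0
  sqrt(sum(d[1:2]^2))
}

#' Apply a pose to points
#' @param pose a [pose_z()].
#' @param pts numeric triple or n x 3 matrix of (y, x, z) points.
#' @return transformed points, same shape.
#' @export
pose_transform_points <- function(pose, pts) {
  one <- is.null(dim(pts))
  p <- if (one) matrix(pts, 1) else as.matrix(pts)
  ct <- cos(pose$theta_rad); st <- sin(pose$theta_rad)
  y <- p[, 1]; x <- p[, 2]; z <- p[, 3]
  yn <- pose$scale * (st * x + ct * y) + pose$translation[1]
  xn <- pose$scale * (ct * x - st * y) + pose$translation[2]
  sz <- if (pose$scale_z) pose$scale else 1
  zn <- sz * z + pose$translation[3]
  out <- unname(cbind(yn, xn, zn))
  if (one) out[1, ] else out
}

#' Invert a pose
#' @param pose a [pose_z()].
#' @return the inverse [pose_z()].
#' @export
pose_invert <- function(pose) {
  sz <- if (pose$scale_z) pose$scale else 1
  ct <- cos(-pose$theta_rad); st <- sin(-pose$theta_rad)
  t <- pose$translation
  # inverse of p' = sRp + t is p = R^-1 (p' - t) / s
  ty <- (st * (-t[2]) + ct * (-t[1])) / pose$scale
  tx <- (ct * (-t[2]) - st * (-t[1])) / pose$scale
  pose_z(-pose$theta_rad, 1 / pose$scale, c(ty, tx, -t[3] / sz),
         scale_z = pose$scale_z)
}

#' Pose aligning a sample landmark line onto a reference line
#'
#' The rotation is the difference of in-plane angles, the scale the ratio of
#' in-plane lengths (reference over sample), and the translation carries the
#' rotated, scaled sample first endpoint onto the reference first endpoint.
#' z is handled by translation only (flat-landed assumption).
#'
#' @param sample,reference [landmark_line()] objects.
#' @param scale_z stretch z by the in-plane factor (default TRUE).
#' @return a [pose_z()] such that `pose_transform_points(pose, sample$p0)`
#'   equals `reference$p0` and the in-plane image of `sample$p1` equals the
#'   in-plane `reference$p1`.
#' @export
pose_from_landmarks <- function(sample, reference, scale_z = TRUE) {
  assert_that(inherits(sample, "landmark_line") &&
                inherits(reference, "landmark_line"),
              "sample and reference must be landmark_line objects")
  theta <- line_angle(reference) - line_angle(sample)
  scale <- line_inplane_length(reference) / line_inplane_length(sample)
  base <- pose_z(theta, scale, c(0, 0, 0), scale_z = scale_z)
  moved <- pose_transform_points(base, sample$p0)
  pose_z(theta, scale, reference$p0 - moved, scale_z = scale_z)
}

# Bilinear sample of a matrix at fractional 0-based (y, x); outside -> 0.
bilinear_sample <- function(img, ys, xs) {
  nr <- nrow(img); nc <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  get <- function(yy, xx) {
    ok <- yy >= 0 & yy <= nr - 1 & xx >= 0 & xx <= nc - 1
    v <- numeric(length(yy))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  get(y0, x0) * (1 - fy) * (1 - fx) + get(y0 + 1, x0) * fy * (1 - fx) +
    get(y0, x0 + 1) * (1 - fy) * fx + get(y0 + 1, x0 + 1) * fy * fx
}

nearest_sample <- function(img, ys, xs) {
  nr <- nrow(img); nc <- ncol(img)
  yy <- round(ys); xx <- round(xs)
  ok <- yy >= 0 & yy <= nr - 1 & xx >= 0 & xx <= nc - 1
  v <- numeric(length(ys))
  v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
  v
}

#' Resample a stack under a pose
#'
#' Inverse-mapped resampling: every output voxel center is pulled back
#' through the inverse pose and the input is interpolated there. Out-of-
#' bounds voxels are filled with 0. Use `order = 0` (nearest neighbour) for
#' label volumes and `order = 1` (trilinear) for intensities.
#'
#' @param stack an [image_stack()] or 3D array.
#' @param pose a [pose_z()], mapping input coordinates to output coordinates.
#' @param out_shape integer triple (y, x, z); default the input shape.
#' @param order 0 (nearest) or 1 (trilinear).
#' @return object of the same kind as `stack` (array in, array out).
#' @export
apply_pose <- function(stack, pose, out_shape = NULL, order = 1L) {
  v <- stack_data(stack)
  d <- dim(v)
  out_shape <- if (is.null(out_shape)) d else as.integer(as_triple(out_shape, "out_shape"))
  assert_that(all(out_shape >= 1), "out_shape must be positive")
  inv <- pose_invert(pose)
  # in-plane source coordinates are shared by all z
  gy <- rep(seq_len(out_shape[1]) - 1, times = out_shape[2])
  gx <- rep(seq_len(out_shape[2]) - 1, each = out_shape[1])
  ct <- cos(inv$theta_rad); st <- sin(inv$theta_rad)
  ys <- inv$scale * (st * gx + ct * gy) + inv$translation[1]
  xs <- inv$scale * (ct * gx - st * gy) + inv$translation[2]
  szi <- if (inv$scale_z) inv$scale else 1
  out <- array(0, out_shape)
  for (z in seq_len(out_shape[3])) {
    zs <- szi * (z - 1) + inv$translation[3]
    if (order == 0L) {
      zi <- round(zs)
      if (zi < 0 || zi > d[3] - 1) next
      out[, , z] <- matrix(nearest_sample(v[, , zi + 1], ys, xs),
                           out_shape[1], out_shape[2])
    } else {
      z0 <- floor(zs); fz <- zs - z0
      plane <- numeric(length(ys))
      if (z0 >= 0 && z0 <= d[3] - 1)
        plane <- plane + (1 - fz) * bilinear_sample(v[, , z0 + 1], ys, xs)
      if (fz > 0 && z0 + 1 >= 0 && z0 + 1 <= d[3] - 1)
        plane <- plane + fz * bilinear_sample(v[, , z0 + 2], ys, xs)
      out[, , z] <- matrix(plane, out_shape[1], out_shape[2])
    }
  }
  if (inherits(stack, "image_stack"))
    image_stack(out, spacing_um = stack$spacing_um, channel = stack$channel)
  else out
}
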