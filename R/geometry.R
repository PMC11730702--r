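#' Pinhole camera intrinsics
#'
#' Constructs the intrinsic model of an (already undistorted) endoscopic
#' camera. The convention throughout the package: the camera looks down +z,
#' x points right, y points down, and pixel `(0, 0)` is the *center* of the
#' top-left pixel (0-based pixel coordinates).
#'
#' @param fx,fy Focal lengths in pixels (must be positive).
#' @param cx,cy Principal point in pixels, `0 <= cx < width`,
#'   `0 <= cy < height`.
#' @param width,height Image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' K <- camera_intrinsics(70, 70, 31.5, 31.5, 64, 64)
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1,
            cx >= 0, cx < width, cy >= 0, cy < height)
  structure(list(fx = as.numeric(fx), fy = as.numeric(fy),
                 cx = as.numeric(cx), cy = as.numeric(cy),
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: %dx%d, fx=%.3f fy=%.3f cx=%.3f cy=%.3f\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Rigid camera pose (world-to-camera)
#'
#' A pose maps world coordinates into camera coordinates:
#' `x_cam = R %*% x_world + t`. Trajectory files in TUM format store the
#' opposite (camera-to-world) convention and are converted on read by
#' [read_tum_trajectory()].
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation vector.
#' @return An object of class `pose`.
#' @export
pose <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("pose rotation must be orthonormal with determinant +1")
  structure(list(R = R, t = t), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat("pose (world->camera), camera center:",
      sprintf("%.4f", camera_center(x)), "\n")
  invisible(x)
}

#' Compose two poses
#'
#' `pose_compose(p2, p1)` is the pose that first applies `p1`, then `p2`
#' (i.e. the matrix product `T2 %*% T1`).
#' @param p2,p1 `pose` objects.
#' @return A `pose`.
#' @export
pose_compose <- function(p2, p1) {
  pose(p2$R %*% p1$R, as.numeric(p2$R %*% p1$t) + p2$t)
}

#' Invert a pose
#' @param p A `pose`.
#' @return The inverse `pose` (camera-to-world if `p` is world-to-camera).
#' @export
pose_inverse <- function(p) {
  pose(t(p$R), -as.numeric(t(p$R) %*% p$t))
}

#' Apply a pose to 3D points
#' @param p A `pose`.
#' @param pts Nx3 matrix (or length-3 vector) of points.
#' @return Nx3 matrix of transformed points.
#' @export
pose_apply <- function(p, pts) {
  pts <- rbind3(pts)
  sweep(pts %*% t(p$R), 2, -p$t)
}

#' Camera center in world coordinates
#' @param p A world-to-camera `pose`.
#' @return Length-3 vector `-R^T t`.
#' @export
camera_center <- function(p) as.numeric(-t(p$R) %*% p$t)

# coerce a 3-vector or Nx3 matrix to Nx3 matrix
rbind3 <- function(pts) {
  if (is.null(dim(pts))) matrix(as.numeric(pts), ncol = 3) else
    matrix(as.numeric(pts), ncol = 3)
}

#' Project world points into a camera
#'
#' Perspective projection with the package's pixel convention (0-based,
#' pixel centers at integer coordinates). Points at or behind the camera
#' plane are flagged invalid rather than raising an error.
#'
#' @param points Nx3 matrix of world points.
#' @param pose World-to-camera [pose()].
#' @param intrinsics [camera_intrinsics()].
#' @return A list with `uv` (Nx2 pixel coordinates), `depth` (camera-frame
#'   z), and `valid` (logical; `FALSE` for points with z <= 0).
#' @examples
#' K <- camera_intrinsics(70, 70, 31.5, 31.5, 64, 64)
#' project_points(c(0, 0, 5), pose(), K)$uv  # principal point
#' @export
project_points <- function(points, pose, intrinsics) {
  pc <- pose_apply(pose, points)
  z <- pc[, 3]
  valid <- is.finite(z) & z > 1e-12
  u <- intrinsics$fx * pc[, 1] / z + intrinsics$cx
  v <- intrinsics$fy * pc[, 2] / z + intrinsics$cy
  uv <- cbind(u, v)
  uv[!valid, ] <- NA_real_
  list(uv = uv, depth = z, valid = valid)
}

#' Unproject pixels to world points
#'
#' Inverse of [project_points()] on its valid domain: lifts pixel
#' coordinates at known camera-frame depth back to world coordinates.
#'
#' @param uv Nx2 matrix (or length-2 vector) of pixel coordinates.
#' @param depth Camera-frame depth(s), strictly positive, recycled to N.
#' @param pose World-to-camera [pose()].
#' @param intrinsics [camera_intrinsics()].
#' @return Nx3 matrix of world points.
#' @export
unproject_pixels <- function(uv, depth, pose, intrinsics) {
  uv <- matrix(as.numeric(uv), ncol = 2)
  depth <- rep_len(as.numeric(depth), nrow(uv))
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("unproject_pixels: depth must be finite and > 0")
  x <- (uv[, 1] - intrinsics$cx) / intrinsics$fx * depth
  y <- (uv[, 2] - intrinsics$cy) / intrinsics$fy * depth
  pc <- cbind(x, y, depth)
  pose_apply(pose_inverse(pose), pc)
}

#' Per-pixel viewing ray directions (camera frame)
#'
#' Returns the un-normalized camera-frame direction `K^{-1} (u, v, 1)` for
#' every pixel, as an H x W x 3 array. Multiplying by depth gives the
#' camera-space point map used for depth-to-normal conversion.
#' @param intrinsics [camera_intrinsics()].
#' @return H x W x 3 array of ray directions (z component is 1).
#' @export
pixel_ray_directions <- function(intrinsics) {
  H <- intrinsics$height; W <- intrinsics$width
  u <- matrix(rep(0:(W - 1), each = H), H, W)
  v <- matrix(rep(0:(H - 1), times = W), H, W)
  d <- array(0, c(H, W, 3))
  d[, , 1] <- (u - intrinsics$cx) / intrinsics$fx
  d[, , 2] <- (v - intrinsics$cy) / intrinsics$fy
  d[, , 3] <- 1
  d
}

# --- quaternion utilities (w, x, y, z) ---------------------------------------

#' Convert a unit quaternion to a rotation matrix
#' @param q length-4 quaternion `(w, x, y, z)`; normalized internally.
#' @return 3x3 rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#' @param R 3x3 rotation matrix.
#' @return length-4 quaternion `(w, x, y, z)` with non-negative w.
#' @export
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Construct a frame
#'
#' A frame bundles one keyframe's RGB image with its calibrated camera and
#' optional disparity / pseudo-depth / normal maps.
#'
#' @param index Integer frame index.
#' @param image H x W x 3 array in `[0, 1]`.
#' @param pose World-to-camera [pose()].
#' @param intrinsics [camera_intrinsics()].
#' @param disparity Optional H x W map in `[0, 1]`.
#' @param pseudo_depth Optional H x W metric depth map (mm); `NA` = invalid.
#' @param normal Optional H x W x 3 unit-normal map (camera frame).
#' @return An object of class `video_frame`.
#' @export
video_frame <- function(index, image, pose, intrinsics, disparity = NULL,
                  pseudo_depth = NULL, normal = NULL) {
  H <- intrinsics$height; W <- intrinsics$width
  stopifnot(length(dim(image)) == 3, all(dim(image) == c(H, W, 3)))
  chk <- function(m, nm) {
    if (!is.null(m) && !all(dim(m)[1:2] == c(H, W)))
      stop(sprintf("frame: %s size does not match intrinsics", nm))
  }
  chk(disparity, "disparity"); chk(pseudo_depth, "pseudo_depth")
  chk(normal, "normal")
  structure(list(index = as.integer(index), image = image, pose = pose,
                 intrinsics = intrinsics, disparity = disparity,
                 pseudo_depth = pseudo_depth, normal = normal),
            class = "frame")
}

#' Bilinear interpolation of a map at sub-pixel locations
#'
#' Samples an H x W map at 0-based sub-pixel coordinates; used to look up
#' disparity at tracked-point observations. Locations outside the image (or
#' whose 4-neighbourhood contains an NA) return NA.
#'
#' @param map H x W numeric matrix.
#' @param uv Nx2 matrix of 0-based pixel coordinates (u = column, v = row).
#' @return Numeric vector of interpolated values.
#' @export
bilinear_sample <- function(map, uv) {
  uv <- matrix(as.numeric(uv), ncol = 2)
  H <- nrow(map); W <- ncol(map)
  u <- uv[, 1]; v <- uv[, 2]
  u0 <- floor(u); v0 <- floor(v)
  # clamp so u0, u0+1 are valid; treat exact right/bottom edge gracefully
  u0 <- pmin(pmax(u0, 0), W - 2); v0 <- pmin(pmax(v0, 0), H - 2)
  du <- u - u0; dv <- v - v0
  inside <- u >= 0 & u <= W - 1 & v >= 0 & v <= H - 1 &
    is.finite(u) & is.finite(v)
  i00 <- cbind(v0 + 1, u0 + 1); i01 <- cbind(v0 + 1, u0 + 2)
  i10 <- cbind(v0 + 2, u0 + 1); i11 <- cbind(v0 + 2, u0 + 2)
  val <- (1 - dv) * ((1 - du) * map[i00] + du * map[i01]) +
    dv * ((1 - du) * map[i10] + du * map[i11])
  val[!inside] <- NA_real_
  val
}
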