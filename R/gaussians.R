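#' Explicit 3D Gaussian scene representation
#'
#' Stores N anisotropic 3D Gaussians: world positions (mm), per-axis scales
#' kept as log-scales (activated by `exp`), unit-quaternion rotations
#' `(w, x, y, z)`, opacities kept as logits (activated by the logistic
#' function), and degree-0 RGB colors.
#'
#' @param positions Nx3 matrix of world positions.
#' @param log_scales Nx3 matrix of log scales.
#' @param rotations Nx4 matrix of quaternions (normalized internally).
#' @param opacity_logits Length-N vector of opacity logits.
#' @param colors Nx3 matrix of RGB colors in `[0, 1]`.
#' @return An object of class `gaussian_cloud`.
#' @export
gaussian_cloud <- function(positions, log_scales, rotations, opacity_logits,
                           colors) {
  positions <- rbind3(positions)
  N <- nrow(positions)
  log_scales <- matrix(as.numeric(log_scales), N, 3)
  rotations <- matrix(as.numeric(rotations), N, 4)
  rotations <- rotations / sqrt(rowSums(rotations^2))
  colors <- matrix(as.numeric(colors), N, 3)
  stopifnot(length(opacity_logits) == N)
  structure(list(positions = positions, log_scales = log_scales,
                 rotations = rotations,
                 opacity_logits = as.numeric(opacity_logits),
                 colors = colors),
            class = "gaussian_cloud")
}

#' @export
print.gaussian_cloud <- function(x, ...) {
  cat(sprintf("gaussian_cloud: %d Gaussians, mean opacity %.3f\n",
              nrow(x$positions), mean(opacities(x))))
  invisible(x)
}

#' Number of Gaussians in a cloud
#' @param cloud A `gaussian_cloud`.
#' @return Integer count.
#' @export
n_gaussians <- function(cloud) nrow(cloud$positions)

#' Activated opacities of a cloud
#' @param cloud A `gaussian_cloud`.
#' @return Vector of opacities in (0, 1).
#' @export
opacities <- function(cloud) 1 / (1 + exp(-cloud$opacity_logits))

#' Activated (positive) scales of a cloud
#' @param cloud A `gaussian_cloud`.
#' @return Nx3 matrix of scales.
#' @export
scales <- function(cloud) exp(cloud$log_scales)

logit <- function(p) log(p / (1 - p))

#' Initialize a Gaussian cloud from a sparse point cloud
#'
#' One Gaussian per point: isotropic initial scale equal to the mean distance
#' to the point's 3 nearest neighbours (floored at `min_scale` so duplicate
#' points stay finite), identity rotation, initial opacity 0.1, and colors
#' taken from the supplied per-point RGB samples.
#'
#' @param points Nx3 matrix of 3D points (e.g. the sparse SLAM prior).
#' @param colors Nx3 matrix of RGB in `[0, 1]`; a single color is recycled.
#' @param initial_opacity Initial activated opacity (default 0.1).
#' @param min_scale Lower bound on the initial scale (mm).
#' @return A `gaussian_cloud`.
#' @export
init_from_points <- function(points, colors = c(0.5, 0.5, 0.5),
                             initial_opacity = 0.1, min_scale = 1e-4) {
  points <- rbind3(points)
  N <- nrow(points)
  if (N < 1) stop("init_from_points: empty point set")
  if (is.null(dim(colors))) colors <- matrix(colors, N, 3, byrow = TRUE)
  k <- min(3, N - 1)
  if (k >= 1) {
    kn <- knn_cpp(points, points, k + 1)      # first neighbour is the point itself
    d <- rowMeans(kn$dist[, -1, drop = FALSE])
  } else d <- rep(min_scale, N)
  d <- pmax(d, min_scale)
  gaussian_cloud(points, matrix(log(d), N, 3),
                 matrix(rep(c(1, 0, 0, 0), each = N), N, 4),
                 rep(logit(initial_opacity), N), colors)
}

#' Render a Gaussian cloud into a camera
#'
#' Differentiable EWA-style CPU rasterization: each Gaussian is projected
#' perspectively, its 2D covariance is `J W Sigma W' J' + 0.3 I`, and
#' Gaussians are alpha-composited front-to-back in camera-depth order.
#' Returns the RGB image over `bg`, the alpha-normalized expected depth, the
#' composited (renormalized) per-Gaussian normals -- each Gaussian's normal is
#' the rotation axis of its smallest activated scale, flipped toward the
#' camera -- and the accumulated alpha.
#'
#' @param cloud A `gaussian_cloud`.
#' @param pose World-to-camera [pose()].
#' @param intrinsics [camera_intrinsics()].
#' @param bg Background RGB (default black).
#' @param flag Optional logical/integer vector (length N) marking a subset of
#'   Gaussians; the output then also carries `flag_weight`, the per-pixel
#'   compositing weight accumulated by the flagged subset.
#' @return A list of class `render_output` with `image` (H x W x 3), `depth`
#'   (H x W, 0 where alpha is 0), `normal` (H x W x 3 unit vectors), `alpha`
#'   (H x W), and optionally `flag_weight`.
#' @export
render_gaussians <- function(cloud, pose, intrinsics, bg = c(0, 0, 0),
                             flag = NULL) {
  if (n_gaussians(cloud) < 1) stop("render_gaussians: empty cloud")
  fl <- if (is.null(flag)) integer(0) else as.integer(as.logical(flag))
  out <- splat_render_cpp(cloud$positions, cloud$log_scales, cloud$rotations,
                          cloud$opacity_logits, cloud$colors,
                          pose$R, pose$t, intrinsics$fx, intrinsics$fy,
                          intrinsics$cx, intrinsics$cy,
                          intrinsics$width, intrinsics$height,
                          as.numeric(bg), fl)
  class(out) <- "render_output"
  out
}

# backward: per-pixel adjoints of (image, depth, normal, alpha) -> parameter
# gradients. g is a list with entries image, depth, normal, alpha (any may be
# all-zero arrays).
render_gaussians_vjp <- function(cloud, pose, intrinsics, bg, g) {
  splat_backward_cpp(cloud$positions, cloud$log_scales, cloud$rotations,
                     cloud$opacity_logits, cloud$colors,
                     pose$R, pose$t, intrinsics$fx, intrinsics$fy,
                     intrinsics$cx, intrinsics$cy,
                     intrinsics$width, intrinsics$height,
                     as.numeric(bg), g$image, g$depth, g$normal, g$alpha)
}

#' Export the positions of sufficiently opaque Gaussians
#'
#' The trained splat model doubles as a dense point cloud: the positions of
#' all Gaussians whose activated opacity reaches `threshold`.
#'
#' @param cloud A `gaussian_cloud`.
#' @param threshold Opacity cutoff (default 0.5).
#' @return Mx3 matrix of world positions.
#' @export
export_point_cloud <- function(cloud, threshold = 0.5) {
  cloud$positions[opacities(cloud) >= threshold, , drop = FALSE]
}

# subset a cloud by a logical/integer index
subset_cloud <- function(cloud, idx) {
  gaussian_cloud(cloud$positions[idx, , drop = FALSE],
                 cloud$log_scales[idx, , drop = FALSE],
                 cloud$rotations[idx, , drop = FALSE],
                 cloud$opacity_logits[idx],
                 cloud$colors[idx, , drop = FALSE])
}
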