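# AR operators on a trained Gaussian-splat scene: point picking and Euclidean
# measurement, and mask-anchored annotation that persists across viewpoints.

#' Pick a 3D point on the rendered scene
#'
#' Unprojects a pixel at the rendered depth and averages the `k` nearest
#' Gaussian centers (Euclidean distance in world space, among Gaussians with
#' activated opacity >= 0.5; distance ties broken by lower index), which
#' denoises the depth estimate at the pick.
#'
#' @param cloud A `gaussian_cloud`.
#' @param view World-to-camera [pose()] of the rendered view.
#' @param intrinsics [camera_intrinsics()].
#' @param pixel Length-2 pixel coordinate `(u, v)`, 0-based.
#' @param k Number of nearest Gaussians to average (default 8).
#' @param render Optional precomputed [render_gaussians()] output for this
#'   view (rendered internally if omitted).
#' @return A list of class `picked_point`: `pixel`, `world_point`,
#'   `contributing_gaussians` (indices into the cloud), `view`.
#' @export
pick_point <- function(cloud, view, intrinsics, pixel, k = 8, render = NULL) {
  if (is.null(render)) render <- render_gaussians(cloud, view, intrinsics)
  u <- round(pixel[1]); v <- round(pixel[2])
  if (u < 0 || u >= intrinsics$width || v < 0 || v >= intrinsics$height)
    stop("pick_point: pixel outside the image")
  a <- render$alpha[v + 1, u + 1]
  if (!is.finite(a) || a <= 0.5)
    stop("pick_point: no surface at this pixel (alpha <= 0.5)")
  d <- render$depth[v + 1, u + 1]
  p <- unproject_pixels(c(pixel[1], pixel[2]), d, view, intrinsics)
  sel <- which(opacities(cloud) >= 0.5)
  if (length(sel) == 0) stop("pick_point: no opaque Gaussians in the cloud")
  kk <- min(k, length(sel))
  kn <- knn_cpp(matrix(p, 1, 3), cloud$positions[sel, , drop = FALSE], kk)
  idx <- sel[kn$idx[1, ]]
  structure(list(pixel = c(pixel[1], pixel[2]),
                 world_point = colMeans(cloud$positions[idx, , drop = FALSE]),
                 contributing_gaussians = idx, view = view),
            class = "picked_point")
}

#' Measure the Euclidean distance between two picked points
#'
#' Distance in model units (mm once the model is metrically consistent);
#' absolute scale against an external reference is meaningful only after
#' similarity alignment.
#'
#' @inheritParams pick_point
#' @param pixel_a,pixel_b Length-2 pixel coordinates of the two picks.
#' @return Distance (scalar) with attribute `picks` holding both
#'   `picked_point`s.
#' @export
measure_distance <- function(cloud, view, intrinsics, pixel_a, pixel_b,
                             k = 8, render = NULL) {
  if (is.null(render)) render <- render_gaussians(cloud, view, intrinsics)
  pa <- pick_point(cloud, view, intrinsics, pixel_a, k, render)
  pb <- pick_point(cloud, view, intrinsics, pixel_b, k, render)
  d <- sqrt(sum((pa$world_point - pb$world_point)^2))
  attr(d, "picks") <- list(pa, pb)
  d
}

#' Anchor an annotation mask to 3D Gaussians
#'
#' Selects the Gaussians that generated the masked image region: opaque
#' Gaussians (opacity >= 0.5) whose projected centers fall inside the mask
#' and whose camera depth is within `depth_tolerance` of the rendered depth
#' at that pixel (the depth gate excludes occluded background Gaussians,
#' since a 2D mask alone cannot distinguish them).
#'
#' @param cloud A `gaussian_cloud`.
#' @param view World-to-camera [pose()] the mask was drawn in.
#' @param intrinsics [camera_intrinsics()].
#' @param mask H x W binary/logical mask.
#' @param depth_tolerance Depth gate (mm); default `2 *` the median mean
#'   activated Gaussian scale.
#' @param highlight_color RGB used when re-rendering the annotation.
#' @param render Optional precomputed render for this view.
#' @return A list of class `annotation_anchor`: `gaussian_indices`,
#'   `highlight_color`, `source_mask`, `source_view`. Empty selection gives
#'   an empty anchor with a warning.
#' @export
anchor_annotation <- function(cloud, view, intrinsics, mask,
                              depth_tolerance = NULL,
                              highlight_color = c(0, 1, 0), render = NULL) {
  if (sum(mask > 0) == 0) {
    warning("anchor_annotation: empty mask")
    return(structure(list(gaussian_indices = integer(0),
                          highlight_color = highlight_color,
                          source_mask = mask, source_view = view),
                     class = "annotation_anchor"))
  }
  if (is.null(render)) render <- render_gaussians(cloud, view, intrinsics)
  if (is.null(depth_tolerance))
    depth_tolerance <- 2 * stats::median(rowMeans(scales(cloud)))
  pr <- project_points(cloud$positions, view, intrinsics)
  u <- round(pr$uv[, 1]); v <- round(pr$uv[, 2])
  inside <- pr$valid & !is.na(u) &
    u >= 0 & u < intrinsics$width & v >= 0 & v < intrinsics$height
  sel <- which(inside & opacities(cloud) >= 0.5)
  if (length(sel) > 0) {
    pix <- cbind(v[sel] + 1, u[sel] + 1)
    in_mask <- mask[pix] > 0
    near_surface <- abs(pr$depth[sel] - render$depth[pix]) <= depth_tolerance
    sel <- sel[in_mask & near_surface]
  }
  if (length(sel) == 0)
    warning("anchor_annotation: no Gaussians matched the mask")
  structure(list(gaussian_indices = sel, highlight_color = highlight_color,
                 source_mask = mask, source_view = view),
            class = "annotation_anchor")
}

#' Re-render an anchored annotation from any view
#'
#' Renders the cloud with the anchored Gaussians' colors replaced by the
#' anchor's highlight color, and derives the predicted annotation mask as the
#' pixels where the anchored Gaussians contribute more than half of the
#' accumulated compositing weight.
#'
#' @param cloud A `gaussian_cloud`.
#' @param anchor An [anchor_annotation()] result.
#' @param view World-to-camera [pose()] to render from.
#' @param intrinsics [camera_intrinsics()].
#' @return A list with `image` (highlighted H x W x 3), `mask` (H x W
#'   logical), `render` (the underlying `render_output`).
#' @export
render_annotation <- function(cloud, anchor, view, intrinsics) {
  N <- n_gaussians(cloud)
  idx <- anchor$gaussian_indices
  if (length(idx) > 0 && (min(idx) < 1 || max(idx) > N))
    stop("render_annotation: anchor indices out of bounds for this cloud")
  hl <- cloud
  if (length(idx) > 0)
    hl$colors[idx, ] <- matrix(anchor$highlight_color, length(idx), 3,
                               byrow = TRUE)
  fl <- rep(FALSE, N); fl[idx] <- TRUE
  out <- render_gaussians(hl, view, intrinsics, flag = fl)
  share <- out$flag_weight / pmax(out$alpha, 1e-12)
  mask <- share > 0.5 & out$alpha > 0
  list(image = out$image, mask = mask, render = out)
}

#' Anchor a spherical landmark at a picked point
#'
#' Selects all Gaussians within `radius` of the picked world point. When none
#' fall inside the radius, a decorative (non-optimizable) Gaussian is
#' inserted at the point so the landmark is still visible; the returned cloud
#' carries a `fixed` attribute flagging it.
#'
#' @param cloud A `gaussian_cloud`.
#' @param picked A [pick_point()] result.
#' @param radius Selection radius (mm).
#' @param highlight_color RGB for rendering the landmark.
#' @return A list with `anchor` (an `annotation_anchor`) and `cloud` (the
#'   possibly extended cloud to render with).
#' @export
anchor_landmark <- function(cloud, picked, radius,
                            highlight_color = c(1, 0, 0)) {
  d <- sqrt(rowSums(sweep(cloud$positions, 2, picked$world_point)^2))
  idx <- which(d <= radius)
  out_cloud <- cloud
  if (length(idx) == 0) {
    ms <- stats::median(rowMeans(scales(cloud)))
    out_cloud <- gaussian_cloud(
      rbind(cloud$positions, picked$world_point),
      rbind(cloud$log_scales, rep(log(max(ms, 1e-4)), 3)),
      rbind(cloud$rotations, c(1, 0, 0, 0)),
      c(cloud$opacity_logits, logit(0.99)),
      rbind(cloud$colors, highlight_color))
    attr(out_cloud, "fixed") <- c(rep(FALSE, n_gaussians(cloud)), TRUE)
    idx <- n_gaussians(out_cloud)
  }
  anchor <- structure(list(gaussian_indices = idx,
                           highlight_color = highlight_color,
                           source_mask = NULL, source_view = picked$view),
                      class = "annotation_anchor")
  list(anchor = anchor, cloud = out_cloud)
}
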