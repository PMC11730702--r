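# Seeded generator of endoscopic-like ground-truth scenes: a smooth
# low-texture articular surface (heightfield of Gaussian bumps, optional
# concave cavity), a camera trajectory pivoting about an entry portal, and
# simulated outputs of the upstream neural components -- sparse SLAM-style 3D
# priors, per-frame min-max-normalized affine-distorted disparity, and
# region masks. Scale convention: 1 unit = 1 mm.

# derive a stage-specific 31-bit seed from a global seed
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1000003 + h * 7919) %% 2147483647)
}

#' Synthetic scene configuration
#'
#' Defaults emulate knee-arthroscopy working conditions: a ~50 mm articular
#' surface patch viewed from 8-20 mm by a camera pivoting about a fixed entry
#' portal, 100 frames with every 5th frame kept as a keyframe, 64x64 images.
#'
#' @param motion One of `"pivoting"` (camera tip swings on a sphere about the
#'   portal), `"forward_backward"` (translation along the scope axis), or
#'   `"common"` (both combined).
#' @param n_frames Number of trajectory frames.
#' @param width,height Image size in pixels.
#' @param keyframe_stride Keep every n-th frame as a keyframe (default 5).
#' @param focal Focal length in pixels (fx = fy).
#' @param domain Surface half-extent in mm (surface spans `2 * domain`).
#' @param n_bumps Range (length-2) of the number of Gaussian surface bumps.
#' @param bump_amp Maximum bump amplitude (mm, both signs).
#' @param bump_sigma Range of bump widths (mm).
#' @param cavity Add one concave cavity region (logical).
#' @param cavity_depth,cavity_radius Cavity depth and radius (mm).
#' @param n_regions Number of Voronoi surface regions (for masks).
#' @param portal Entry portal point (world, mm).
#' @param scope_length Portal-to-tip distance (mm) for pivoting motion.
#' @param scope_range Range of portal-to-tip distances for forward/backward.
#' @param pivot_angle Maximum pivot tilt from the portal axis (degrees).
#' @param texture_contrast Amplitude of the mottled albedo variation.
#' @param ambient Ambient share of the headlight Lambertian shading in
#'   `[0, 1]`; the remainder varies with viewing angle.
#' @param disparity_noise Disparity noise, relative to the per-frame raw
#'   disparity range.
#' @param n_prior_points Sparse-prior size (also the initial Gaussian count).
#' @param pixel_noise_sd Sparse-prior observation noise (pixels).
#' @param depth_noise_rel Sparse-prior 3D point noise, relative to depth.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(motion = c("common", "pivoting", "forward_backward"),
                         n_frames = 100, width = 64, height = 64,
                         keyframe_stride = 5, focal = 70, domain = 25,
                         n_bumps = c(5, 20), bump_amp = 3,
                         bump_sigma = c(5, 15), cavity = TRUE,
                         cavity_depth = 6, cavity_radius = 8, n_regions = 4,
                         portal = c(0, 0, -30), scope_length = 16,
                         scope_range = c(10, 22), pivot_angle = 15,
                         texture_contrast = 0.15, ambient = 0.7,
                         disparity_noise = 0.01, n_prior_points = 2000,
                         pixel_noise_sd = 0.5, depth_noise_rel = 0.01) {
  motion <- match.arg(motion)
  structure(as.list(environment()), class = "scene_config")
}

#' Generate a synthetic ground-truth scene
#'
#' Deterministic in `(config, seed)`. The surface is a smooth random
#' heightfield `z = f(x, y)` (sum of Gaussian bumps, optional concave
#' cavity), textured with low-contrast mottled color; the trajectory obeys
#' the configured portal-constrained motion; per-frame ground-truth affine
#' disparity parameters are drawn for the disparity simulator.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_scene`: `config`, `seed`, `bumps`
#'   (bump parameter matrix), `region_seeds`, `texture` (blob matrix),
#'   `base_color`, `trajectory` (list of [pose()]), `intrinsics`,
#'   `true_affine` (per-frame data.frame with `A`, `B`), `keyframes`
#'   (frame indices).
#' @export
make_scene <- function(config = scene_config(), seed = 0) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "scene"))
  cfg <- config
  nb <- sample(cfg$n_bumps[1]:cfg$n_bumps[2], 1)
  bumps <- cbind(stats::runif(nb, -0.7, 0.7) * cfg$domain,
                 stats::runif(nb, -0.7, 0.7) * cfg$domain,
                 stats::runif(nb, cfg$bump_sigma[1], cfg$bump_sigma[2]),
                 stats::runif(nb, -cfg$bump_amp, cfg$bump_amp))
  cavity_row <- NULL
  if (isTRUE(cfg$cavity)) {
    # concave = indented away from the camera (the camera sits at z < 0)
    cavity_row <- c(stats::runif(1, -0.4, 0.4) * cfg$domain,
                    stats::runif(1, -0.4, 0.4) * cfg$domain,
                    cfg$cavity_radius, cfg$cavity_depth)
    bumps <- rbind(bumps, cavity_row)
  }
  colnames(bumps) <- c("x", "y", "sigma", "amp")
  region_seeds <- cbind(stats::runif(cfg$n_regions, -0.8, 0.8) * cfg$domain,
                        stats::runif(cfg$n_regions, -0.8, 0.8) * cfg$domain)
  ntex <- 30
  texture <- cbind(stats::runif(ntex, -1, 1) * cfg$domain,
                   stats::runif(ntex, -1, 1) * cfg$domain,
                   stats::runif(ntex, 3, 10),
                   matrix(stats::runif(ntex * 3, -cfg$texture_contrast,
                                       cfg$texture_contrast), ntex, 3))
  base_color <- c(0.75, 0.45, 0.40)
  n <- cfg$n_frames
  tt <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  th_max <- cfg$pivot_angle * pi / 180
  if (cfg$motion == "pivoting") {
    theta <- th_max * sin(pi * tt)
    phi <- 4 * pi * tt
    L <- rep(cfg$scope_length, n)
  } else if (cfg$motion == "forward_backward") {
    theta <- rep(5 * pi / 180, n)
    phi <- rep(pi / 4, n)
    mid <- mean(cfg$scope_range); amp <- diff(cfg$scope_range) / 2
    L <- mid + amp * sin(4 * pi * tt)
  } else {
    theta <- th_max * 0.8 * sin(pi * tt)
    phi <- 3 * pi * tt
    mid <- mean(cfg$scope_range); amp <- diff(cfg$scope_range) / 3
    L <- mid + amp * sin(4 * pi * tt)
  }
  trajectory <- vector("list", n)
  for (i in seq_len(n)) {
    a <- c(sin(theta[i]) * cos(phi[i]), sin(theta[i]) * sin(phi[i]),
           cos(theta[i]))
    cc <- cfg$portal + L[i] * a
    zax <- a
    xax <- c(zax[3], 0, -zax[1]); xax <- xax / sqrt(sum(xax^2))
    yax <- c(zax[2] * xax[3] - zax[3] * xax[2],   # y = z x x (right-handed)
             zax[3] * xax[1] - zax[1] * xax[3],
             zax[1] * xax[2] - zax[2] * xax[1])
    R_c2w <- cbind(xax, yax, zax)
    R <- t(R_c2w)
    trajectory[[i]] <- pose(R, -as.numeric(R %*% cc))
  }
  cx <- (cfg$width - 1) / 2; cy <- (cfg$height - 1) / 2
  intr <- camera_intrinsics(cfg$focal, cfg$focal, cx, cy,
                            cfg$width, cfg$height)
  true_affine <- data.frame(frame = seq_len(n),
                            A = stats::runif(n, 5, 15),
                            B = stats::runif(n, 0, 10))
  scene <- structure(
    list(config = cfg, seed = seed, bumps = bumps,
         cavity = cavity_row, region_seeds = region_seeds,
         texture = texture, base_color = base_color,
         trajectory = trajectory, intrinsics = intr,
         true_affine = true_affine,
         keyframes = seq(1, n, by = cfg$keyframe_stride)),
    class = "synthetic_scene")
  # feasibility: every camera center must sit clear of the surface, and the
  # surface must fill at least half of every view
  for (i in seq_len(n)) {
    cc <- camera_center(trajectory[[i]])
    fz <- heightfield_eval_cpp(scene$bumps, cc[1], cc[2])$z
    if (cc[3] > fz - 2)
      stop("make_scene: infeasible config (camera/portal inside the surface)")
  }
  hit <- render_ground_truth(scene, 1)$hit
  if (mean(hit) < 0.5)
    stop("make_scene: infeasible config (surface fills < 50% of the view)")
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic_scene: %d frames (%d keyframes), %dx%d, motion '%s', seed %d\n",
    x$config$n_frames, length(x$keyframes), x$config$width, x$config$height,
    x$config$motion, x$seed))
  invisible(x)
}

#' Surface height, gradient and region label at (x, y)
#'
#' Evaluates the scene's heightfield `z = f(x, y)`, its gradient, and the
#' region label (Voronoi region of the nearest region seed; the cavity
#' overrides with its own label `n_regions + 1` inside its half-depth
#' contour).
#'
#' @param scene A `synthetic_scene`.
#' @param x,y Coordinates (mm), vectorized.
#' @return A list with `z`, `gx`, `gy`, `label`.
#' @export
surface_at <- function(scene, x, y) {
  hf <- heightfield_eval_cpp(scene$bumps, x, y)
  ns <- nrow(scene$region_seeds)
  d2 <- vapply(seq_len(ns), function(k)
    (x - scene$region_seeds[k, 1])^2 + (y - scene$region_seeds[k, 2])^2,
    numeric(length(x)))
  d2 <- matrix(d2, ncol = ns)
  label <- max.col(-d2, ties.method = "first")
  if (!is.null(scene$cavity)) {
    cv <- scene$cavity
    contrib <- cv[4] * exp(-0.5 * ((x - cv[1])^2 + (y - cv[2])^2) / cv[3]^2)
    label[contrib > cv[4] / 2] <- ns + 1L
  }
  list(z = hf$z, gx = hf$gx, gy = hf$gy, label = label)
}

# mottled albedo at surface points
.albedo_at <- function(scene, x, y) {
  tex <- scene$texture
  alb <- matrix(scene$base_color, length(x), 3, byrow = TRUE)
  for (k in seq_len(nrow(tex))) {
    w <- exp(-0.5 * ((x - tex[k, 1])^2 + (y - tex[k, 2])^2) / tex[k, 3]^2)
    alb <- alb + outer(w, tex[k, 4:6])
  }
  pmin(pmax(alb, 0.05), 0.95)
}

#' Ray-cast ground-truth render of a scene frame
#'
#' Casts a ray through every pixel, intersects it with the heightfield, and
#' shades hits with the mottled albedo under headlight Lambertian
#' illumination (`ambient + (1 - ambient) * <n, -d>`), mimicking an
#' endoscope's light source moving with the camera. Misses get the
#' background color and depth 0.
#'
#' @param scene A `synthetic_scene`.
#' @param frame_index Frame number (1-based).
#' @param bg Background RGB.
#' @return A list with `image` (H x W x 3), `depth` (H x W camera-frame z,
#'   0 at misses), `hit` (H x W logical).
#' @export
render_ground_truth <- function(scene, frame_index, bg = c(0, 0, 0)) {
  stopifnot(frame_index >= 1, frame_index <= length(scene$trajectory))
  K <- scene$intrinsics
  p <- scene$trajectory[[frame_index]]
  H <- K$height; W <- K$width
  dirs_cam <- pixel_ray_directions(K)
  dc <- cbind(as.vector(dirs_cam[, , 1]), as.vector(dirs_cam[, , 2]),
              as.vector(dirs_cam[, , 3]))
  Rw <- t(p$R)
  dw <- dc %*% t(Rw)
  cc <- camera_center(p)
  origins <- matrix(cc, nrow(dw), 3, byrow = TRUE)
  # camera-frame z of a hit equals the ray parameter (dirs have z_cam = 1)
  t_hit <- raycast_heightfield_cpp(scene$bumps, origins, dw, 1, 60, 300,
                                   scene$config$domain)
  hit <- !is.na(t_hit)
  depth <- ifelse(hit, t_hit, 0)
  img <- matrix(bg, nrow(dw), 3, byrow = TRUE)
  if (any(hit)) {
    ph <- origins[hit, , drop = FALSE] + t_hit[hit] * dw[hit, , drop = FALSE]
    sf <- surface_at(scene, ph[, 1], ph[, 2])
    # camera-facing surface normal of z = f(x, y): (gx, gy, -1)/|.|
    nrm <- cbind(sf$gx, sf$gy, -1)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    dn <- dw[hit, , drop = FALSE] / sqrt(rowSums(dw[hit, , drop = FALSE]^2))
    lam <- pmax(0, -rowSums(nrm * dn))
    shade <- scene$config$ambient + (1 - scene$config$ambient) * lam
    img[hit, ] <- .albedo_at(scene, ph[, 1], ph[, 2]) * shade
  }
  img <- pmin(pmax(img, 0), 1)
  image <- array(0, c(H, W, 3))
  for (c in 1:3) image[, , c] <- matrix(img[, c], H, W)
  list(image = image, depth = matrix(depth, H, W), hit = matrix(hit, H, W))
}

#' Simulate a monocular-depth-network disparity map
#'
#' Produces the per-frame min-max-normalized affine distortion of true depth
#' that a relative-depth network would deliver: `raw = (depth - B) / A` on
#' hit pixels, plus i.i.d. Gaussian noise of sd `noise_sigma`, then min-max
#' normalized to `[0, 1]` over hit pixels. Misses are `NA`. A constant depth
#' map cannot be normalized; it is flagged degenerate and set to 0.5.
#'
#' @param depth_gt H x W ground-truth depth (0 or `NA` = miss).
#' @param A_true,B_true True affine parameters (A != 0).
#' @param noise_sigma Noise sd in raw-disparity units.
#' @param seed Integer seed.
#' @return H x W disparity map in `[0, 1]` with attributes `A_eff`, `B_eff`
#'   (the post-normalization effective affine parameters such that
#'   `depth ~ A_eff * disparity + B_eff`) and `degenerate`.
#' @export
simulate_disparity <- function(depth_gt, A_true, B_true, noise_sigma = 0,
                               seed = 0) {
  stopifnot(A_true != 0)
  hit <- is.finite(depth_gt) & depth_gt > 0
  if (!any(hit)) stop("simulate_disparity: no hit pixels")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "disparity"))
  raw <- (depth_gt - B_true) / A_true
  if (noise_sigma > 0) raw[hit] <- raw[hit] + stats::rnorm(sum(hit), 0,
                                                           noise_sigma)
  lo <- min(raw[hit]); hi <- max(raw[hit])
  out <- matrix(NA_real_, nrow(depth_gt), ncol(depth_gt))
  if (hi - lo < 1e-12) {
    out[hit] <- 0.5
    attr(out, "degenerate") <- TRUE
    attr(out, "A_eff") <- NA_real_; attr(out, "B_eff") <- NA_real_
    return(out)
  }
  out[hit] <- (raw[hit] - lo) / (hi - lo)
  attr(out, "A_eff") <- A_true * (hi - lo)
  attr(out, "B_eff") <- A_true * lo + B_true
  attr(out, "degenerate") <- FALSE
  out
}

#' Build keyframe objects with ground-truth renders and simulated disparity
#'
#' Renders every keyframe of the scene and attaches a simulated disparity map
#' (per-frame affine distortion of the true depth, using the scene's
#' per-frame true `(A, B)` and the configured relative noise level).
#'
#' @param scene A `synthetic_scene`.
#' @param seed Integer seed for the disparity noise.
#' @param disparity_noise Override of `config$disparity_noise` (relative to
#'   the per-frame raw disparity range; 0 = noiseless).
#' @return A list with `frames` (list of [video_frame()] objects, one per
#'   keyframe, with `image`, `disparity` and ground-truth `depth`/`hit`
#'   attached), and `effective_affine` (data.frame: frame, A_eff, B_eff).
#' @export
scene_keyframes <- function(scene, seed = 0, disparity_noise = NULL) {
  if (is.null(disparity_noise)) disparity_noise <- scene$config$disparity_noise
  kf <- scene$keyframes
  frames <- vector("list", length(kf))
  eff <- data.frame(frame = kf, A_eff = NA_real_, B_eff = NA_real_)
  for (j in seq_along(kf)) {
    i <- kf[j]
    gt <- render_ground_truth(scene, i)
    A <- scene$true_affine$A[i]; B <- scene$true_affine$B[i]
    hit <- gt$depth > 0
    raw_range <- diff(range((gt$depth[hit] - B) / A))
    disp <- simulate_disparity(gt$depth, A, B,
                               noise_sigma = disparity_noise * raw_range,
                               seed = derive_seed(seed, paste0("disp", i)))
    fr <- video_frame(i, gt$image, scene$trajectory[[i]], scene$intrinsics,
                disparity = disp)
    fr$gt_depth <- gt$depth
    fr$hit <- gt$hit
    eff$A_eff[j] <- attr(disp, "A_eff"); eff$B_eff[j] <- attr(disp, "B_eff")
    frames[[j]] <- fr
  }
  list(frames = frames, effective_affine = eff)
}

#' Simulate a sparse SLAM-style 3D prior
#'
#' Samples surface points uniformly over the visible area (union of keyframe
#' views), records their noisy per-keyframe 2D observations (projection +
#' Gaussian pixel noise), perturbs the stored 3D points with depth-relative
#' noise, and flags per-keyframe visibility via an occlusion test against the
#' ground-truth depth maps.
#'
#' @param scene A `synthetic_scene`.
#' @param n_points Number of tracked points (>= 10).
#' @param pixel_noise_sd Observation noise sd (pixels); default from config.
#' @param depth_noise_rel 3D point noise sd relative to the point's mean
#'   observed depth; default from config.
#' @param seed Integer seed.
#' @return A list of class `sparse_prior`: `points` (stored, noisy Nx3),
#'   `true_points` (Nx3), `colors` (Nx3), `observations` (data.frame with
#'   `point`, `frame`, `u`, `v`), `keyframes`.
#' @export
simulate_sparse_prior <- function(scene, n_points = NULL,
                                  pixel_noise_sd = NULL,
                                  depth_noise_rel = NULL, seed = 0) {
  cfg <- scene$config
  if (is.null(n_points)) n_points <- cfg$n_prior_points
  if (is.null(pixel_noise_sd)) pixel_noise_sd <- cfg$pixel_noise_sd
  if (is.null(depth_noise_rel)) depth_noise_rel <- cfg$depth_noise_rel
  if (n_points < 10) stop("simulate_sparse_prior: n_points must be >= 10")
  kf <- scene$keyframes
  gts <- lapply(kf, function(i) render_ground_truth(scene, i))
  pool <- sum(vapply(gts, function(g) sum(g$hit), 0))
  if (n_points > pool)
    stop("simulate_sparse_prior: n_points exceeds available visible samples")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "prior"))
  K <- scene$intrinsics
  # sample surface points through random hit pixels of random keyframes
  fsel <- sample.int(length(kf), n_points, replace = TRUE)
  pts <- matrix(0, n_points, 3)
  cols <- matrix(0, n_points, 3)
  for (j in seq_len(n_points)) {
    g <- gts[[fsel[j]]]
    hp <- which(g$hit)
    pix <- hp[sample.int(length(hp), 1)]
    v <- (pix - 1) %% K$height; u <- (pix - 1) %/% K$height
    pts[j, ] <- unproject_pixels(c(u, v), g$depth[pix],
                                 scene$trajectory[[kf[fsel[j]]]], K)
    cols[j, ] <- g$image[cbind(v + 1, u + 1, 1:3)]
  }
  obs <- list(); depth_sum <- numeric(n_points); depth_n <- numeric(n_points)
  for (j in seq_along(kf)) {
    pr <- project_points(pts, scene$trajectory[[kf[j]]], K)
    u <- pr$uv[, 1]; v <- pr$uv[, 2]
    eps <- 1e-6  # tolerate edge-of-image floating-point wobble
    inb <- pr$valid & u >= -eps & u <= K$width - 1 + eps &
      v >= -eps & v <= K$height - 1 + eps
    ucl <- pmin(pmax(u[inb], 0), K$width - 1)
    vcl <- pmin(pmax(v[inb], 0), K$height - 1)
    zmap <- bilinear_sample(gts[[j]]$depth, cbind(ucl, vcl))
    occl_ok <- is.finite(zmap) & abs(zmap - pr$depth[inb]) < 0.02 * pr$depth[inb] + 0.1
    vis <- which(inb)[occl_ok]
    if (length(vis) > 0) {
      nu <- u[vis] + stats::rnorm(length(vis), 0, pixel_noise_sd)
      nv <- v[vis] + stats::rnorm(length(vis), 0, pixel_noise_sd)
      obs[[length(obs) + 1]] <- data.frame(point = vis, frame = kf[j],
                                           u = nu, v = nv)
      depth_sum[vis] <- depth_sum[vis] + pr$depth[vis]
      depth_n[vis] <- depth_n[vis] + 1
    }
  }
  obs <- do.call(rbind, obs)
  mean_depth <- ifelse(depth_n > 0, depth_sum / pmax(depth_n, 1),
                       mean(depth_sum[depth_n > 0] / depth_n[depth_n > 0]))
  stored <- pts
  if (depth_noise_rel > 0)
    stored <- pts + matrix(stats::rnorm(3 * n_points), n_points, 3) *
      (depth_noise_rel * mean_depth)
  structure(list(points = stored, true_points = pts, colors = cols,
                 observations = obs, keyframes = kf),
            class = "sparse_prior")
}

#' @export
print.sparse_prior <- function(x, ...) {
  cat(sprintf("sparse_prior: %d points, %d observations over %d keyframes\n",
              nrow(x$points), nrow(x$observations), length(x$keyframes)))
  invisible(x)
}

#' Ground-truth region mask for a frame
#'
#' Binary mask of the pixels whose first-hit surface point carries the given
#' region label (standing in for an interactive segmentation output).
#'
#' @param scene A `synthetic_scene`.
#' @param region_label Integer label (Voronoi regions `1..n_regions`; the
#'   cavity, when present, is `n_regions + 1`).
#' @param frame_index Frame number.
#' @return H x W logical mask (with a warning if the label is absent).
#' @export
simulate_mask <- function(scene, region_label, frame_index) {
  K <- scene$intrinsics
  gt <- render_ground_truth(scene, frame_index)
  mask <- matrix(FALSE, K$height, K$width)
  if (any(gt$hit)) {
    p <- scene$trajectory[[frame_index]]
    dirs_cam <- pixel_ray_directions(K)
    dc <- cbind(as.vector(dirs_cam[, , 1]), as.vector(dirs_cam[, , 2]),
                as.vector(dirs_cam[, , 3]))
    dw <- dc %*% p$R
    cc <- camera_center(p)
    hv <- which(as.vector(gt$hit))
    ph <- matrix(cc, length(hv), 3, byrow = TRUE) +
      as.vector(gt$depth)[hv] * dw[hv, , drop = FALSE]
    lab <- surface_at(scene, ph[, 1], ph[, 2])$label
    mask[hv] <- lab == region_label
  }
  if (!any(mask))
    warning(sprintf("simulate_mask: label %d absent in frame %d",
                    region_label, frame_index))
  mask
}

#' Triangle mesh of the scene's ground-truth surface
#'
#' Regular-grid triangulation of the heightfield over its domain.
#'
#' @param scene A `synthetic_scene`.
#' @param resolution Grid cells per axis (default 128).
#' @return A list with `vertices` (Vx3) and `faces` (Fx3, 1-based).
#' @export
scene_mesh <- function(scene, resolution = 128) {
  d <- scene$config$domain
  g <- seq(-d, d, length.out = resolution + 1)
  xy <- expand.grid(x = g, y = g)
  z <- heightfield_eval_cpp(scene$bumps, xy$x, xy$y)$z
  V <- unname(cbind(xy$x, xy$y, z))
  colnames(V) <- c("x", "y", "z")
  n <- resolution + 1
  i <- rep(seq_len(resolution), resolution)
  j <- rep(seq_len(resolution), each = resolution)
  v00 <- (j - 1) * n + i; v10 <- v00 + 1; v01 <- v00 + n; v11 <- v01 + 1
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  list(vertices = V, faces = faces)
}
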