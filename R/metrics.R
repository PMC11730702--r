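# Evaluation protocol: image metrics (PSNR, SSIM), point-cloud metrics
# (point-to-point RMSE, Hausdorff), similarity ICP alignment, mask mIoU, and
# the randomized AR measurement-error study.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(1 / MSE)` over all channels, for images normalized to
#' `[0, 1]` (peak L = 1). Identical images give `Inf`.
#'
#' @param rendered,target Arrays of identical shape, values in `[0, 1]`.
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
psnr <- function(rendered, target) {
  if (!identical(dim(rendered), dim(target)))
    stop("psnr: shape mismatch")
  mse <- mean((rendered - target)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

# 1D Gaussian kernel, length 11, sigma 1.5 (the standard SSIM window)
.ssim_kernel <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# valid-mode separable Gaussian filter as banded-matrix products; returns the
# two banded matrices for an H x W image
.ssim_bands <- function(H, W, size = 11) {
  k <- .ssim_kernel(size)
  band <- function(n) {
    m <- matrix(0, n - size + 1, n)
    for (i in seq_len(n - size + 1)) m[i, i:(i + size - 1)] <- k
    m
  }
  list(Bh = band(H), Bw = band(W))
}

.as_channels <- function(x) {
  if (is.matrix(x)) list(x) else lapply(seq_len(dim(x)[3]), function(c) x[, , c])
}

# per-channel SSIM statistics; optionally the gradient of mean(SSIM) wrt x
.ssim_channel <- function(x, y, bands, C1, C2, grad = FALSE) {
  F <- function(M) bands$Bh %*% M %*% t(bands$Bw)
  Ft <- function(G) t(bands$Bh) %*% G %*% bands$Bw
  ux <- F(x); uy <- F(y)
  uxx <- F(x * x); uyy <- F(y * y); uxy <- F(x * y)
  vx <- uxx - ux^2; vy <- uyy - uy^2; vxy <- uxy - ux * uy
  A1 <- 2 * ux * uy + C1; A2 <- 2 * vxy + C2
  B1 <- ux^2 + uy^2 + C1; B2 <- vx + vy + C2
  S <- A1 * A2 / (B1 * B2)
  out <- list(mean = mean(S))
  if (grad) {
    g <- 1 / length(S)
    dS_dux <- 2 * uy * A2 / (B1 * B2) - 2 * ux * A1 * A2 / (B1^2 * B2)
    dS_dvx <- -A1 * A2 / (B1 * B2^2)
    dS_dvxy <- 2 * A1 / (B1 * B2)
    g_ux <- g * (dS_dux + dS_dvx * (-2 * ux) + dS_dvxy * (-uy))
    g_uxx <- g * dS_dvx
    g_uxy <- g * dS_dvxy
    out$grad <- Ft(g_ux) + 2 * x * Ft(g_uxx) + y * Ft(g_uxy)
  }
  out
}

#' Structural similarity index
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5), stabilizers
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` at peak `L = 1`, computed over the
#' valid (fully-windowed) region and averaged over pixels and channels.
#'
#' @param rendered,target H x W matrices or H x W x 3 arrays in `[0, 1]`;
#'   both dimensions must be at least 11.
#' @return SSIM score in `[-1, 1]`.
#' @export
ssim <- function(rendered, target) {
  if (!identical(dim(rendered), dim(target)))
    stop("ssim: shape mismatch")
  d <- dim(rendered)
  if (d[1] < 11 || d[2] < 11) stop("ssim: image smaller than the 11x11 window")
  bands <- .ssim_bands(d[1], d[2])
  xs <- .as_channels(rendered); ys <- .as_channels(target)
  C1 <- 0.01^2; C2 <- 0.03^2
  mean(vapply(seq_along(xs), function(c)
    .ssim_channel(xs[[c]], ys[[c]], bands, C1, C2)$mean, 0))
}

# value and gradient of ssim(x, y) wrt x (same conventions as ssim())
ssim_with_grad <- function(x, y) {
  d <- dim(x)
  bands <- .ssim_bands(d[1], d[2])
  xs <- .as_channels(x); ys <- .as_channels(y)
  C1 <- 0.01^2; C2 <- 0.03^2
  vals <- numeric(length(xs))
  grads <- if (is.matrix(x)) matrix(0, d[1], d[2]) else array(0, d)
  for (c in seq_along(xs)) {
    r <- .ssim_channel(xs[[c]], ys[[c]], bands, C1, C2, grad = TRUE)
    vals[c] <- r$mean
    if (is.matrix(x)) grads <- r$grad / length(xs)
    else grads[, , c] <- r$grad / length(xs)
  }
  list(value = mean(vals), grad = grads)
}

#' Mean intersection-over-union of two mask sequences
#'
#' Per-frame IoU `|A & B| / |A | B|` (1 when both masks are empty), averaged
#' over frames.
#'
#' @param predicted,reference Lists (or single matrices) of binary/logical
#'   masks, frame-aligned and of equal length.
#' @return Mean IoU in `[0, 1]`.
#' @export
miou <- function(predicted, reference) {
  if (is.matrix(predicted)) predicted <- list(predicted)
  if (is.matrix(reference)) reference <- list(reference)
  if (length(predicted) != length(reference))
    stop("miou: mask lists have different lengths")
  ious <- mapply(function(p, r) {
    if (!identical(dim(p), dim(r))) stop("miou: mask shape mismatch")
    p <- p > 0; r <- r > 0
    u <- sum(p | r)
    if (u == 0) 1 else sum(p & r) / u
  }, predicted, reference)
  mean(ious)
}

#' Point-to-point RMSE between aligned clouds
#'
#' For each source point, the distance to its nearest target point; returns
#' the root mean square of those distances (source -> target direction).
#'
#' @param source,target Nx3 / Mx3 point matrices (mm).
#' @return RMSE in the clouds' length units.
#' @export
rmse_point_to_point <- function(source, target) {
  source <- rbind3(source); target <- rbind3(target)
  if (nrow(source) == 0 || nrow(target) == 0)
    stop("rmse_point_to_point: empty cloud")
  d <- nn_cpp(source, target)$dist
  sqrt(mean(d^2))
}

#' Symmetric Hausdorff distance between point clouds
#'
#' Maximum of the two directed max-min distances.
#'
#' @param source,target Nx3 / Mx3 point matrices.
#' @return Hausdorff distance in the clouds' length units.
#' @export
hausdorff_distance <- function(source, target) {
  source <- rbind3(source); target <- rbind3(target)
  if (nrow(source) == 0 || nrow(target) == 0)
    stop("hausdorff_distance: empty cloud")
  max(max(nn_cpp(source, target)$dist), max(nn_cpp(target, source)$dist))
}

#' Sample points uniformly from a triangle mesh surface
#'
#' Area-weighted triangle selection followed by uniform barycentric
#' sampling; deterministic for a given seed.
#'
#' @param mesh A list with `vertices` (Vx3) and `faces` (Fx3, 1-based).
#' @param n Number of points.
#' @param seed Integer seed.
#' @return An `n` x 3 matrix of surface points.
#' @export
sample_mesh <- function(mesh, n, seed = 1) {
  V <- rbind3(mesh$vertices); Fc <- matrix(as.integer(mesh$faces), ncol = 3)
  if (nrow(Fc) < 1) stop("sample_mesh: mesh has no faces")
  a <- V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 2], , drop = FALSE]
  cc <- V[Fc[, 3], , drop = FALSE]
  cr <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
              (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
              (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  area <- 0.5 * sqrt(rowSums(cr^2))
  if (sum(area) <= 0) stop("sample_mesh: degenerate mesh (zero total area)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tri <- sample.int(nrow(Fc), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  w1 * a[tri, , drop = FALSE] + w2 * b[tri, , drop = FALSE] +
    w3 * cc[tri, , drop = FALSE]
}

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  } else assign(".Random.seed", old, envir = .GlobalEnv)
}

# closed-form similarity (scale + rigid) fit of paired points: finds s, R, t
# minimizing sum |s R x + t - y|^2 (Umeyama/Procrustes solution)
similarity_fit <- function(X, Y) {
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / n
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- mean(rowSums(Xc^2))
  s <- sum(diag(D) * sv$d) / varx
  t <- my - s * as.numeric(R %*% mx)
  list(scale = s, R = R, t = t)
}

apply_similarity <- function(X, s, R, t) {
  sweep(s * X %*% t(R), 2, -t)
}

# principal-axis rotations of a centered cloud (proper orthonormal)
.pca_axes <- function(X) {
  E <- eigen(stats::cov(X), symmetric = TRUE)$vectors
  if (det(E) < 0) E[, 3] <- -E[, 3]
  E
}

#' Similarity ICP alignment of two point clouds
#'
#' Aligns `source` to `target` with a 7-DoF similarity transform (global
#' scale, rotation, translation), as monocular reconstructions are defined
#' only up to scale. Initialization matches centroids, RMS spreads, and
#' principal axes (all four proper axis-sign combinations are tried as
#' starts, plus identity); each start is refined by iterating
#' nearest-neighbour correspondence and the closed-form similarity fit until
#' the RMSE improvement drops below `tol`; the best start wins.
#'
#' @param source,target Nx3 / Mx3 point matrices (>= 3 non-collinear points).
#' @param max_iter Maximum ICP iterations per start (default 100).
#' @param tol Stop when the RMSE improves by less than this (default 1e-6).
#' @return A list of class `alignment_result`: `scale`, `rotation`,
#'   `translation` (mapping source into the target frame), `rmse_after`,
#'   `iterations_used`, `converged`, `rmse_trace`, and `aligned` (the
#'   transformed source).
#' @export
align_icp <- function(source, target, max_iter = 100, tol = 1e-6) {
  source <- rbind3(source); target <- rbind3(target)
  if (nrow(source) < 3 || nrow(target) < 3)
    stop("align_icp: need at least 3 points in each cloud")
  ms <- colMeans(source); mt <- colMeans(target)
  ss <- sqrt(mean(rowSums(sweep(source, 2, ms)^2)))
  st <- sqrt(mean(rowSums(sweep(target, 2, mt)^2)))
  s0 <- if (ss > 0) st / ss else 1
  Es <- .pca_axes(source); Et <- .pca_axes(target)
  starts <- list(diag(3))
  for (sgn in list(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))) {
    D <- diag(c(sgn[1], sgn[2], sgn[1] * sgn[2]))  # det +1
    starts[[length(starts) + 1]] <- Et %*% D %*% t(Es)
  }
  run_icp <- function(s, R, t, iter_budget, trace = numeric(0)) {
    rmse_prev <- if (length(trace)) trace[length(trace)] else Inf
    iters <- 0; converged <- FALSE
    for (it in seq_len(iter_budget)) {
      Xa <- apply_similarity(source, s, R, t)
      nn <- nn_cpp(Xa, target)
      rmse <- sqrt(mean(nn$dist^2))
      trace <- c(trace, rmse)
      iters <- it
      if (rmse_prev - rmse < tol) { converged <- TRUE; break }
      if (s < 1e-6 * s0 || s > 1e6 * s0) break  # scale collapse/blow-up
      rmse_prev <- rmse
      fit <- similarity_fit(source, target[nn$idx, , drop = FALSE])
      s <- fit$scale; R <- fit$R; t <- fit$t
    }
    list(scale = s, rotation = R, translation = t,
         rmse_after = trace[length(trace)], iterations_used = iters,
         converged = converged, rmse_trace = trace)
  }
  # phase 1: a short coarse pass per start, scored symmetrically (a
  # degenerate scale collapse can reach zero source->target RMSE while
  # leaving the target uncovered); phase 2 refines only the winner
  best <- NULL; best_score <- Inf
  for (R0 in starts) {
    s <- s0; R <- R0; t <- mt - s * as.numeric(R %*% ms)
    cand <- run_icp(s, R, t, min(20, max_iter))
    Xa <- apply_similarity(source, cand$scale, cand$rotation,
                           cand$translation)
    score <- sqrt(mean(nn_cpp(Xa, target)$dist^2)) +
      sqrt(mean(nn_cpp(target, Xa)$dist^2))
    if (is.null(best) || score < best_score) { best <- cand
      best_score <- score }
  }
  if (!best$converged && max_iter > 20) {
    more <- run_icp(best$scale, best$rotation, best$translation,
                    max_iter - 20, trace = best$rmse_trace)
    more$iterations_used <- more$iterations_used + best$iterations_used
    best <- more
  }
  best$aligned <- apply_similarity(source, best$scale, best$rotation,
                                   best$translation)
  class(best) <- "alignment_result"
  best
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("similarity ICP: scale %.5f, rmse %.6g after %d iterations%s\n",
              x$scale, x$rmse_after, x$iterations_used,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Randomized AR measurement-error study
#'
#' Emulates the measurement validation protocol: random pixel pairs are
#' picked on rendered views of the reconstructed scene, each pair is measured
#' with the AR tool, the picked endpoints are matched to their nearest
#' ground-truth surface points, and the AR distances are compared with the
#' ground-truth distances.
#'
#' @param scene A [make_scene()] synthetic scene providing the ground truth.
#' @param cloud The trained `gaussian_cloud` (in the scene's metric frame; an
#'   alignment can be applied beforehand if needed).
#' @param n_pairs Number of measured pairs (default 500).
#' @param seed Integer seed for pair selection.
#' @param k Nearest-Gaussian averaging size for point picking.
#' @param gt_samples Number of ground-truth surface samples used for
#'   correspondence lookup.
#' @param gt_points Optional explicit ground-truth surface points (Nx3);
#'   overrides `gt_samples`.
#' @return A list with `pairs` (data.frame: view, pixel coordinates, AR and
#'   ground-truth distances, error) and `summary` (mean, sd, median,
#'   quartiles of the absolute error, the median ground-truth pair distance,
#'   and counts). A warning is raised if fewer than `n_pairs` valid picks are
#'   found within `10 * n_pairs` attempts.
#' @export
measurement_error_study <- function(scene, cloud, n_pairs = 500, seed = 1,
                                    k = 8, gt_samples = 100000,
                                    gt_points = NULL) {
  K <- scene$intrinsics
  kf <- scene$keyframes
  gt <- if (is.null(gt_points))
    sample_mesh(scene_mesh(scene), gt_samples, seed = seed + 1L)
  else rbind3(gt_points)
  renders <- lapply(kf, function(i)
    render_gaussians(cloud, scene$trajectory[[i]], K))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- vector("list", n_pairs)
  got <- 0; attempts <- 0; max_attempts <- 10 * n_pairs
  while (got < n_pairs && attempts < max_attempts) {
    attempts <- attempts + 1
    vi <- sample.int(length(kf), 1)
    px <- matrix(c(sample.int(K$width, 2) - 1, sample.int(K$height, 2) - 1), 2)
    p1 <- try(pick_point(cloud, scene$trajectory[[kf[vi]]], K, px[1, ], k,
                         render = renders[[vi]]), silent = TRUE)
    p2 <- try(pick_point(cloud, scene$trajectory[[kf[vi]]], K, px[2, ], k,
                         render = renders[[vi]]), silent = TRUE)
    if (inherits(p1, "try-error") || inherits(p2, "try-error")) next
    d_ar <- sqrt(sum((p1$world_point - p2$world_point)^2))
    g1 <- gt[nn_cpp(matrix(p1$world_point, 1), gt)$idx, ]
    g2 <- gt[nn_cpp(matrix(p2$world_point, 1), gt)$idx, ]
    d_gt <- sqrt(sum((g1 - g2)^2))
    got <- got + 1
    rows[[got]] <- data.frame(view = kf[vi], u1 = px[1, 1], v1 = px[1, 2],
                              u2 = px[2, 1], v2 = px[2, 2],
                              d_ar = d_ar, d_gt = d_gt,
                              error = abs(d_ar - d_gt))
  }
  if (got < n_pairs)
    warning(sprintf("measurement_error_study: only %d/%d valid pairs", got,
                    n_pairs))
  pairs <- do.call(rbind, rows[seq_len(got)])
  qs <- stats::quantile(pairs$error, c(0.25, 0.5, 0.75), names = FALSE)
  list(pairs = pairs,
       summary = list(n = got, attempts = attempts,
                      mean = mean(pairs$error), sd = stats::sd(pairs$error),
                      q25 = qs[1], median = qs[2], q75 = qs[3],
                      median_gt_distance = stats::median(pairs$d_gt)))
}
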