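# Per-keyframe recovery of the affine disparity-to-depth mapping
# D_pseudo = A * d + B from 2D-3D correspondences between the disparity map
# and the sparse 3D prior, producing temporally consistent metric
# pseudo-depth across keyframes.

#' Collect 2D-3D correspondences for a keyframe
#'
#' For every prior point observed in the frame: the disparity sampled at the
#' observed pixel (bilinear interpolation) and the camera-frame z of the
#' stored 3D point. Observations outside the image, on invalid disparity, or
#' behind the camera are dropped.
#'
#' @param prior A `sparse_prior`.
#' @param frame A [video_frame()] with a disparity map.
#' @return A data.frame with `point`, `u`, `v`, `disparity`, `depth`
#'   (possibly zero rows).
#' @export
collect_correspondences <- function(prior, frame) {
  if (is.null(frame$disparity))
    stop("collect_correspondences: frame has no disparity map")
  obs <- prior$observations[prior$observations$frame == frame$index, ,
                            drop = FALSE]
  if (nrow(obs) == 0)
    return(data.frame(point = integer(0), u = numeric(0), v = numeric(0),
                      disparity = numeric(0), depth = numeric(0)))
  d <- bilinear_sample(frame$disparity, cbind(obs$u, obs$v))
  z <- pose_apply(frame$pose, prior$points[obs$point, , drop = FALSE])[, 3]
  keep <- is.finite(d) & is.finite(z) & z > 0
  data.frame(point = obs$point[keep], u = obs$u[keep], v = obs$v[keep],
             disparity = d[keep], depth = z[keep])
}

#' Fit the affine disparity-to-depth parameters
#'
#' Minimizes `sum (X_z - (A x_d + B))^2` over the correspondences with
#' Nelder-Mead, initialized at the closed-form ordinary-least-squares
#' solution (relative tolerance 1e-10, at most 500 iterations) -- so the
#' achieved objective can never exceed the OLS optimum beyond numerical
#' tolerance. A negative fitted scale is allowed but warned about.
#'
#' @param correspondences Data.frame from [collect_correspondences()] (needs
#'   columns `disparity` and `depth`), or a list/data.frame with those
#'   columns.
#' @param frame_index Frame index stored in the result.
#' @param trim Single pass of residual trimming: drop correspondences whose
#'   absolute residual exceeds 3x the median absolute deviation and refit
#'   once (off by default; a stress-test knob for drifting track points).
#' @param inverse_disparity Fit depth as affine in *inverse* shifted
#'   disparity, `D = A / (d + 0.5) + B`, instead of the default affine-in-d
#'   model (off by default; the 0.5 shift keeps the min-max-normalized zero
#'   disparity finite).
#' @return A list of class `affine_depth_params`: `A`, `B`, `frame_index`,
#'   `residual_rms`, `n_correspondences`, `objective`, `inverse_disparity`.
#' @export
fit_affine <- function(correspondences, frame_index = NA_integer_,
                       trim = FALSE, inverse_disparity = FALSE) {
  x <- correspondences$disparity; z <- correspondences$depth
  if (inverse_disparity) x <- 1 / (x + 0.5)
  fit1 <- .fit_affine_core(x, z)
  if (trim) {
    res <- abs(z - (fit1$A * x + fit1$B))
    keep <- res <= 3 * stats::mad(res) + 1e-12
    if (sum(keep) >= 2 && any(!keep)) fit1 <- .fit_affine_core(x[keep],
                                                               z[keep])
  }
  if (fit1$A < 0)
    warning("fit_affine: negative scale A (check the disparity convention)")
  structure(c(fit1, list(frame_index = frame_index,
                         inverse_disparity = inverse_disparity)),
            class = "affine_depth_params")
}

.fit_affine_core <- function(x, z) {
  n <- length(x)
  if (n < 2) stop("fit_affine: need at least 2 correspondences")
  if (stats::sd(x) < 1e-12)
    stop("fit_affine: degenerate fit (constant disparity)")
  ols <- stats::lm.fit(cbind(x, 1), z)$coefficients
  sse <- function(p) sum((z - (p[1] * x + p[2]))^2)
  opt <- stats::optim(ols, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  p <- if (opt$value <= sse(ols)) opt$par else ols
  list(A = unname(p[1]), B = unname(p[2]),
       residual_rms = sqrt(sse(p) / n), n_correspondences = n,
       objective = sse(p))
}

#' @export
print.affine_depth_params <- function(x, ...) {
  cat(sprintf(
    "affine_depth_params (frame %s): A=%.6g B=%.6g, rms %.4g mm over n=%d\n",
    format(x$frame_index), x$A, x$B, x$residual_rms, x$n_correspondences))
  invisible(x)
}

#' Map a disparity map to pseudo-depth
#'
#' Elementwise `D_pseudo = A * d + B`. Pixels where the result is
#' non-positive (or disparity invalid) are set to `NA` and thereby excluded
#' from all downstream losses.
#'
#' @param disparity H x W disparity map in `[0, 1]`.
#' @param params An [fit_affine()] result (or any list with `A`, `B`).
#' @return H x W pseudo-depth map (mm) with `NA` at invalid pixels.
#' @export
to_pseudo_depth <- function(disparity, params) {
  x <- if (isTRUE(params$inverse_disparity)) 1 / (disparity + 0.5) else
    disparity
  d <- params$A * x + params$B
  d[!is.finite(d) | d <= 0] <- NA_real_
  d
}

#' Recover affine parameters for a keyframe sequence
#'
#' Fits `(A, B)` independently per keyframe and reports the temporal
#' consistency of the resulting pseudo-depth: for every prior point seen in
#' more than one keyframe, its per-frame pseudo-depth pick is unprojected to
#' a world point, and the maximum pairwise disagreement between those world
#' points is recorded. Keyframes whose fit fails (too few correspondences,
#' constant disparity) are excluded with a warning and listed in the report.
#'
#' @param prior A `sparse_prior`.
#' @param frames List of keyframe [video_frame()]s with disparity maps.
#' @return A list with `params` (list of `affine_depth_params`, one per
#'   successful keyframe), `pseudo_depth` (list of maps, `NULL` for failed
#'   frames), `failed` (frame indices), and `consistency` (data.frame:
#'   `point`, `n_frames`, `max_disagreement_mm`).
#' @export
recover_sequence <- function(prior, frames) {
  params <- list(); pseudo <- vector("list", length(frames))
  failed <- integer(0)
  for (j in seq_along(frames)) {
    fr <- frames[[j]]
    co <- collect_correspondences(prior, fr)
    fit <- try(fit_affine(co, fr$index), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning(sprintf("recover_sequence: keyframe %d excluded (%s)",
                      fr$index, attr(fit, "condition")$message))
      failed <- c(failed, fr$index)
      next
    }
    params[[length(params) + 1]] <- fit
    pseudo[[j]] <- to_pseudo_depth(fr$disparity, fit)
  }
  # temporal-consistency report at shared track points
  world <- list()
  for (j in seq_along(frames)) {
    if (is.null(pseudo[[j]])) next
    fr <- frames[[j]]
    obs <- prior$observations[prior$observations$frame == fr$index, ,
                              drop = FALSE]
    if (nrow(obs) == 0) next
    dep <- bilinear_sample(pseudo[[j]], cbind(obs$u, obs$v))
    ok <- is.finite(dep) & dep > 0
    if (!any(ok)) next
    w <- unproject_pixels(cbind(obs$u[ok], obs$v[ok]), dep[ok], fr$pose,
                          fr$intrinsics)
    world[[length(world) + 1]] <- data.frame(point = obs$point[ok],
                                             x = w[, 1], y = w[, 2],
                                             z = w[, 3])
  }
  consistency <- data.frame(point = integer(0), n_frames = integer(0),
                            max_disagreement_mm = numeric(0))
  if (length(world) > 0) {
    all_w <- do.call(rbind, world)
    sp <- split(all_w, all_w$point)
    sp <- sp[vapply(sp, nrow, 0L) >= 2]
    if (length(sp) > 0)
      consistency <- do.call(rbind, lapply(sp, function(g) {
        P <- as.matrix(g[, c("x", "y", "z")])
        dmax <- max(stats::dist(P))
        data.frame(point = g$point[1], n_frames = nrow(g),
                   max_disagreement_mm = dmax)
      }))
    rownames(consistency) <- NULL
  }
  list(params = params, pseudo_depth = pseudo, failed = failed,
       consistency = consistency)
}
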