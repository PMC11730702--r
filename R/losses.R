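# The five training loss terms. All take plain arrays so they can be tested
# in isolation; total_loss() assembles the weighted sum exactly as
# L = (1-l_ssim) L1 + l_ssim (1 - SSIM) + l_d L_d + l_o L_o + l_c L_c + l_n L_n.

#' Loss weights for Gaussian-splat training
#'
#' The combined objective is the photometric term (L1/SSIM mix controlled by
#' `lambda_ssim`) plus depth, opacity, depth-normal consistency and
#' normal-prior regularization. Defaults follow the orders of magnitude used
#' by the upstream splatting literature: `lambda_ssim = 0.2`,
#' `lambda_d = 0.5`, `lambda_c = 0.05`, `lambda_n1 = 0.05`,
#' `lambda_n2 = 0.01`, `lambda_o = 0.01`.
#'
#' @param lambda_ssim SSIM share of the photometric term, in `[0, 1]`.
#' @param lambda_d Weight of the L1 pseudo-depth loss (per mm).
#' @param lambda_o Weight of the opacity binarization loss.
#' @param lambda_c Weight of the depth-normal consistency loss.
#' @param lambda_n1,lambda_n2 Weights of the normal-prior term and the
#'   normal-smoothness (gradient) term.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(lambda_ssim = 0.2, lambda_d = 0.5, lambda_o = 0.01,
                         lambda_c = 0.05, lambda_n1 = 0.05,
                         lambda_n2 = 0.01) {
  w <- list(lambda_ssim = lambda_ssim, lambda_d = lambda_d,
            lambda_o = lambda_o, lambda_c = lambda_c,
            lambda_n1 = lambda_n1, lambda_n2 = lambda_n2)
  stopifnot(all(unlist(w) >= 0), lambda_ssim <= 1)
  structure(w, class = "loss_weights")
}

#' Photometric loss (L1 + D-SSIM mix)
#'
#' `(1 - lambda_ssim) * mean|I_hat - I| + lambda_ssim * (1 - SSIM(I_hat, I))`.
#'
#' @param rendered,target H x W x 3 arrays (or H x W matrices) in `[0, 1]`.
#' @param lambda_ssim Mixing weight in `[0, 1]`.
#' @return Scalar loss.
#' @export
loss_photometric <- function(rendered, target, lambda_ssim = 0.2) {
  if (!identical(dim(rendered), dim(target)))
    stop("loss_photometric: shape mismatch")
  l1 <- mean(abs(rendered - target))
  s <- if (lambda_ssim > 0) ssim(rendered, target) else 1
  (1 - lambda_ssim) * l1 + lambda_ssim * (1 - s)
}

#' Depth loss
#'
#' Mean absolute difference between rendered depth and pseudo-depth over the
#' jointly valid pixels.
#'
#' @param rendered_depth H x W rendered depth map.
#' @param pseudo_depth H x W pseudo-depth map (`NA` = invalid).
#' @param valid Optional additional H x W logical mask (e.g. alpha > 0.5).
#' @return Scalar loss (0 with a warning if no pixel is jointly valid).
#' @export
loss_depth <- function(rendered_depth, pseudo_depth, valid = NULL) {
  m <- is.finite(rendered_depth) & is.finite(pseudo_depth)
  if (!is.null(valid)) m <- m & valid
  if (!any(m)) {
    warning("loss_depth: no jointly valid pixels")
    return(0)
  }
  mean(abs(rendered_depth[m] - pseudo_depth[m]))
}

#' Depth-normal consistency loss
#'
#' `mean(1 - N_hat . N(D_hat))` over valid pixels, where `N(.)` converts the
#' rendered depth map to normals ([depth_to_normal()]). Ranges over `[0, 2]`.
#'
#' @param rendered_normal H x W x 3 rendered unit-normal map.
#' @param rendered_depth H x W rendered depth map.
#' @param intrinsics [camera_intrinsics()].
#' @param valid Optional H x W logical mask (e.g. alpha > 0.5).
#' @return Scalar loss.
#' @export
loss_depth_normal_consistency <- function(rendered_normal, rendered_depth,
                                          intrinsics, valid = NULL) {
  nd <- depth_to_normal(rendered_depth, intrinsics, valid)
  m <- nd$valid
  if (!any(m)) return(0)
  dt <- rendered_normal[, , 1] * nd$normals[, , 1] +
    rendered_normal[, , 2] * nd$normals[, , 2] +
    rendered_normal[, , 3] * nd$normals[, , 3]
  mean(1 - dt[m])
}

#' Normal-prior loss
#'
#' `lambda_n1 * mean(1 - N_hat . N_pseudo) + lambda_n2 * mean(|grad N_hat|)`:
#' agreement with the pseudo-normal map plus an L1 smoothness penalty on the
#' rendered normal's spatial gradient.
#'
#' @param rendered_normal H x W x 3 rendered unit-normal map.
#' @param pseudo_normal H x W x 3 pseudo-normal map (from pseudo-depth).
#' @param lambda_n1,lambda_n2 Term weights.
#' @param valid Optional H x W logical mask.
#' @return Scalar loss.
#' @export
loss_normal_prior <- function(rendered_normal, pseudo_normal,
                              lambda_n1 = 0.05, lambda_n2 = 0.01,
                              valid = NULL) {
  H <- dim(rendered_normal)[1]; W <- dim(rendered_normal)[2]
  if (is.null(valid)) valid <- matrix(TRUE, H, W)
  t1 <- 0
  if (lambda_n1 > 0 && any(valid)) {
    dt <- rendered_normal[, , 1] * pseudo_normal[, , 1] +
      rendered_normal[, , 2] * pseudo_normal[, , 2] +
      rendered_normal[, , 3] * pseudo_normal[, , 3]
    t1 <- mean(1 - dt[valid])
  }
  t2 <- 0
  if (lambda_n2 > 0) {
    g <- normal_gradient(structure(list(normals = rendered_normal,
                                        valid = valid),
                                   class = "normal_map"))
    t2 <- mean(g)
  }
  lambda_n1 * t1 + lambda_n2 * t2
}

#' Opacity binarization loss
#'
#' `mean(exp(-(o - 0.5)^2 / 0.05))` over Gaussians: maximal (1) for
#' half-transparent Gaussians and strictly decreasing as opacities approach 0
#' or 1, so minimizing it pushes opacities toward binary and suppresses
#' translucent floaters.
#'
#' @param opacities Vector of activated opacities in (0, 1).
#' @return Scalar loss.
#' @export
loss_opacity <- function(opacities) {
  mean(exp(-(opacities - 0.5)^2 / 0.05))
}

#' Total training loss with per-term breakdown
#'
#' Weighted sum of the photometric, depth, opacity, depth-normal consistency
#' and normal-prior terms. The geometric terms are evaluated on pixels where
#' the rendered alpha exceeds `alpha_thresh` (intersected with pseudo-depth
#' validity for the depth term).
#'
#' @param render A `render_output` from [render_gaussians()].
#' @param target_image H x W x 3 ground-truth image.
#' @param pseudo_depth H x W pseudo-depth map (`NA` = invalid), or `NULL`.
#' @param pseudo_normal H x W x 3 pseudo-normal map, or `NULL`.
#' @param opacities Activated opacities of the cloud.
#' @param weights [loss_weights()].
#' @param intrinsics [camera_intrinsics()].
#' @param alpha_thresh Validity threshold on rendered alpha (default 0.5).
#' @return A list with `total` and a named `terms` vector
#'   (`pho`, `d`, `o`, `c`, `n`).
#' @export
total_loss <- function(render, target_image, pseudo_depth, pseudo_normal,
                       opacities, weights, intrinsics, alpha_thresh = 0.5) {
  av <- render$alpha > alpha_thresh
  l_pho <- loss_photometric(render$image, target_image, weights$lambda_ssim)
  l_d <- if (!is.null(pseudo_depth) && weights$lambda_d > 0)
    loss_depth(render$depth, pseudo_depth, av) else 0
  l_o <- if (weights$lambda_o > 0) loss_opacity(opacities) else 0
  l_c <- if (weights$lambda_c > 0)
    loss_depth_normal_consistency(render$normal, render$depth, intrinsics, av)
  else 0
  l_n <- if (!is.null(pseudo_normal) &&
             (weights$lambda_n1 > 0 || weights$lambda_n2 > 0))
    loss_normal_prior(render$normal, pseudo_normal,
                      weights$lambda_n1, weights$lambda_n2, av) else 0
  total <- l_pho + weights$lambda_d * l_d + weights$lambda_o * l_o +
    weights$lambda_c * l_c + l_n
  list(total = total, terms = c(pho = l_pho, d = l_d, o = l_o, c = l_c,
                                n = l_n))
}
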