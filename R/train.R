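# Training of the Gaussian-splat model: per-iteration analytic gradients of
# the five-term loss through the renderer, Adam updates with per-group step
# sizes, and periodic opacity pruning.

#' Training configuration for the Gaussian-splat model
#'
#' Step sizes follow the upstream splatting recipe scaled to millimetre
#' units; the position step is multiplied by the scene extent (cloud bounding
#' box diagonal) at train time.
#'
#' @param iterations Number of optimization iterations (default 1500).
#' @param lr Named list of step sizes: `positions` (x scene extent),
#'   `scales`, `rotations`, `opacities`, `colors`.
#' @param prune_interval Prune every this many iterations (0 = never).
#' @param prune_threshold Remove Gaussians with activated opacity below this;
#'   a length-2 vector `c(start, end)` ramps the cutoff linearly over
#'   training, which progressively squeezes out translucent Gaussians while
#'   giving survivors time to turn opaque.
#' @param prune_max_frac At most this fraction of the cloud is removed per
#'   pruning step (lowest opacities first), so the model thins gradually
#'   instead of collapsing at the first prune.
#' @param densify Enable the minimal gradient-threshold clone/split
#'   densification (on by default: pruning thins the cloud into a
#'   near-binary opaque shell and densification refills its spatial
#'   resolution; see the methods vignette).
#' @param densify_interval,densify_grad_threshold Densification cadence and
#'   positional-gradient trigger.
#' @param densify_max_n Densification stops once the cloud reaches this
#'   size.
#' @param alpha_thresh Rendered-alpha validity threshold for the geometric
#'   loss terms.
#' @param bg Background color used during training renders.
#' @param seed Integer seed (densification jitter).
#' @return A list of class `train_config`.
#' @export
train_config <- function(iterations = 1500,
                         lr = list(positions = 2e-4, scales = 5e-3,
                                   rotations = 1e-3, opacities = 5e-2,
                                   colors = 2.5e-3),
                         prune_interval = 150, prune_threshold = 0.3,
                         prune_max_frac = 1, densify = TRUE,
                         densify_interval = 150,
                         densify_grad_threshold = 1e-5, densify_max_n = 2500,
                         alpha_thresh = 0.5, bg = c(0, 0, 0), seed = 0) {
  stopifnot(iterations >= 1)
  structure(as.list(environment()), class = "train_config")
}

# value + per-parameter analytic gradients of the total loss for one view
total_loss_grad <- function(cloud, pose, intrinsics, target_image,
                            pseudo_depth, pseudo_normal, weights,
                            alpha_thresh = 0.5, bg = c(0, 0, 0)) {
  H <- intrinsics$height; W <- intrinsics$width
  out <- render_gaussians(cloud, pose, intrinsics, bg = bg)
  av <- out$alpha > alpha_thresh
  op <- opacities(cloud)
  lv <- total_loss(out, target_image, pseudo_depth, pseudo_normal, op,
                   weights, intrinsics, alpha_thresh)
  gI <- array(0, c(H, W, 3)); gD <- matrix(0, H, W)
  gN <- array(0, c(H, W, 3)); gA <- matrix(0, H, W)
  ls <- weights$lambda_ssim
  # photometric: (1 - ls) L1 + ls (1 - SSIM)
  gI <- gI + (1 - ls) * sign(out$image - target_image) / length(target_image)
  if (ls > 0) {
    sg <- ssim_with_grad(out$image, target_image)
    gI <- gI - ls * sg$grad
  }
  # depth
  if (!is.null(pseudo_depth) && weights$lambda_d > 0) {
    m <- av & is.finite(pseudo_depth)
    if (any(m)) {
      s <- matrix(0, H, W)
      s[m] <- weights$lambda_d * sign(out$depth[m] - pseudo_depth[m]) / sum(m)
      gD <- gD + s
    }
  }
  # depth-normal consistency: mean over valid of (1 - N_hat . N(D_hat))
  if (weights$lambda_c > 0) {
    nd <- .d2n_forward(out$depth, intrinsics, av)
    nv <- sum(nd$valid)
    if (nv > 0) {
      sc <- -weights$lambda_c / nv
      for (c in 1:3)
        gN[, , c] <- gN[, , c] + sc * nd$normals[, , c] * nd$valid
      gnd <- array(0, c(H, W, 3))
      for (c in 1:3) gnd[, , c] <- sc * out$normal[, , c] * nd$valid
      gD <- gD + depth_to_normal_vjp(out$depth, intrinsics, gnd, av)
    }
  }
  # normal prior
  if (!is.null(pseudo_normal) &&
      (weights$lambda_n1 > 0 || weights$lambda_n2 > 0)) {
    if (weights$lambda_n1 > 0 && any(av)) {
      sc <- -weights$lambda_n1 / sum(av)
      for (c in 1:3)
        gN[, , c] <- gN[, , c] + sc * pseudo_normal[, , c] * av
    }
    if (weights$lambda_n2 > 0)
      gN <- gN + normal_gradient_vjp(out$normal, av,
                                     weights$lambda_n2 / (H * W))
  }
  grads <- render_gaussians_vjp(cloud, pose, intrinsics, bg,
                                list(image = gI, depth = gD, normal = gN,
                                     alpha = gA))
  # opacity regularizer acts on the logits directly
  if (weights$lambda_o > 0) {
    N <- n_gaussians(cloud)
    dLo_do <- exp(-(op - 0.5)^2 / 0.05) * (-2 * (op - 0.5) / 0.05) / N
    grads$opacity_logits <- grads$opacity_logits +
      weights$lambda_o * dLo_do * op * (1 - op)
  }
  list(value = lv$total, terms = lv$terms, grads = grads, render = out)
}

# total loss value only (used by the finite-difference gradient checks)
total_loss_value <- function(cloud, pose, intrinsics, target_image,
                             pseudo_depth, pseudo_normal, weights,
                             alpha_thresh = 0.5, bg = c(0, 0, 0)) {
  out <- render_gaussians(cloud, pose, intrinsics, bg = bg)
  total_loss(out, target_image, pseudo_depth, pseudo_normal,
             opacities(cloud), weights, intrinsics, alpha_thresh)$total
}

.adam_new <- function(dims) {
  list(m = lapply(dims, function(d) array(0, d)),
       v = lapply(dims, function(d) array(0, d)), t = 0)
}

#' Train a Gaussian-splat model on keyframes
#'
#' First-order optimization (Adam, per-parameter-group step sizes) of the
#' combined photometric + pseudo-depth + opacity + depth-normal consistency +
#' normal-prior loss. Keyframes are visited round-robin (one view per
#' iteration, deterministic schedule); quaternions are renormalized after
#' every step; Gaussians below the opacity threshold are pruned at the
#' configured interval. Aborts with a diagnostic if the loss turns
#' non-finite.
#'
#' @param cloud Initial `gaussian_cloud` (e.g. [init_from_points()]).
#' @param frames List of keyframe [video_frame()]s carrying `image`,
#'   `pseudo_depth` and (optionally) `normal` maps.
#' @param weights [loss_weights()].
#' @param config [train_config()].
#' @return A list with `cloud` (optimized), `history` (data.frame: iteration,
#'   loss terms, PSNR, Gaussian count), `config`.
#' @export
train_gaussians <- function(cloud, frames, weights = loss_weights(),
                            config = train_config()) {
  if (length(frames) < 2) stop("train_gaussians: need at least 2 keyframes")
  parnames <- c("positions", "log_scales", "rotations", "opacity_logits",
                "colors")
  lrmap <- c(positions = config$lr$positions, log_scales = config$lr$scales,
             rotations = config$lr$rotations,
             opacity_logits = config$lr$opacities,
             colors = config$lr$colors)
  extent <- sqrt(sum((apply(cloud$positions, 2, max) -
                      apply(cloud$positions, 2, min))^2))
  lrmap["positions"] <- lrmap["positions"] * max(extent, 1)
  adam <- .adam_new(lapply(cloud[parnames], dim2))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-15
  hist <- vector("list", config$iterations)
  K <- frames[[1]]$intrinsics
  for (it in seq_len(config$iterations)) {
    fr <- frames[[(it - 1) %% length(frames) + 1]]
    g <- total_loss_grad(cloud, fr$pose, fr$intrinsics, fr$image,
                         fr$pseudo_depth, fr$normal, weights,
                         config$alpha_thresh, config$bg)
    if (!is.finite(g$value))
      stop(sprintf(paste0("train_gaussians: non-finite loss at iteration %d ",
                          "(terms: %s)"), it,
                   paste(sprintf("%s=%.4g", names(g$terms), g$terms),
                         collapse = ", ")))
    adam$t <- adam$t + 1
    for (p in parnames) {
      gr <- g$grads[[p]]
      adam$m[[p]] <- b1 * adam$m[[p]] + (1 - b1) * gr
      adam$v[[p]] <- b2 * adam$v[[p]] + (1 - b2) * gr^2
      mhat <- adam$m[[p]] / (1 - b1^adam$t)
      vhat <- adam$v[[p]] / (1 - b2^adam$t)
      cloud[[p]] <- cloud[[p]] - lrmap[p] * mhat / (sqrt(vhat) + eps)
    }
    cloud$rotations <- cloud$rotations / sqrt(rowSums(cloud$rotations^2))
    hist[[it]] <- data.frame(
      iteration = it, frame = fr$index, total = g$value,
      pho = g$terms["pho"], d = g$terms["d"], o = g$terms["o"],
      c = g$terms["c"], n = g$terms["n"],
      psnr = psnr(pmin(pmax(g$render$image, 0), 1), fr$image),
      n_gaussians = n_gaussians(cloud))
    grads_pos <- g$grads$positions
    if (config$prune_interval > 0 && it %% config$prune_interval == 0 &&
        it < config$iterations) {
      thr <- if (length(config$prune_threshold) == 2)
        config$prune_threshold[1] + diff(config$prune_threshold) *
          it / config$iterations
      else config$prune_threshold
      op <- opacities(cloud)
      keep <- op >= thr
      max_rm <- floor(config$prune_max_frac * length(op))
      if (sum(!keep) > max_rm && max_rm >= 0) {
        # keep the highest-opacity sub-threshold Gaussians for later rounds
        cand <- which(!keep)
        keep[cand[order(op[cand])][-seq_len(max_rm)]] <- TRUE
      }
      if (!all(keep) && sum(keep) > 0) {
        cloud <- subset_cloud(cloud, keep)
        grads_pos <- grads_pos[keep, , drop = FALSE]
        for (p in parnames) {
          adam$m[[p]] <- index_rows(adam$m[[p]], keep)
          adam$v[[p]] <- index_rows(adam$v[[p]], keep)
        }
      }
    }
    if (config$densify && it %% config$densify_interval == 0 &&
        it < config$iterations && n_gaussians(cloud) < config$densify_max_n) {
      res <- densify_cloud(cloud, grads_pos, config, it)
      if (res$changed) {
        cloud <- res$cloud
        adam <- .adam_new(lapply(cloud[parnames], dim2))
      }
    }
  }
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  list(cloud = cloud, history = history, config = config)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)
index_rows <- function(x, keep) {
  if (length(dim(x)) == 2) x[keep, , drop = FALSE] else x[keep]
}

# minimal clone/split densification: Gaussians whose positional gradient norm
# exceeds the threshold are cloned (small ones) or split (large ones)
densify_cloud <- function(cloud, grads_pos, config, it = 0) {
  gn <- sqrt(rowSums(grads_pos^2))
  sel <- which(gn > config$densify_grad_threshold)
  if (length(sel) == 0) return(list(cloud = cloud, changed = FALSE))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed + it, "densify"))
  sc <- scales(cloud)
  big <- rowMeans(sc)[sel] > stats::median(rowMeans(sc))
  add_pos <- cloud$positions[sel, , drop = FALSE] +
    matrix(stats::rnorm(3 * length(sel)), ncol = 3) *
    sc[sel, , drop = FALSE] * 0.3
  add_ls <- cloud$log_scales[sel, , drop = FALSE]
  add_ls[big, ] <- add_ls[big, ] - log(1.6)
  newc <- gaussian_cloud(rbind(cloud$positions, add_pos),
                         rbind(cloud$log_scales, add_ls),
                         rbind(cloud$rotations,
                               cloud$rotations[sel, , drop = FALSE]),
                         c(cloud$opacity_logits, cloud$opacity_logits[sel]),
                         rbind(cloud$colors, cloud$colors[sel, , drop = FALSE]))
  newc$log_scales[sel[big], ] <- newc$log_scales[sel[big], ] - log(1.6)
  list(cloud = newc, changed = TRUE)
}
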