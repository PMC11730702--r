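# shared fixtures: tiny cameras, a flat-plane scene, random Gaussian clouds

tiny_intrinsics <- function(w = 16, h = 16, f = 40) {
  camera_intrinsics(f, f, (w - 1) / 2, (h - 1) / 2, w, h)
}

# flat surface (single zero-amplitude bump), static nadir camera
plane_scene <- function(seed = 1, width = 64, height = 64, n_frames = 10,
                        scope_length = 16) {
  cfg <- scene_config(motion = "pivoting", pivot_angle = 0,
                      n_frames = n_frames, width = width, height = height,
                      n_bumps = c(1, 1), bump_amp = 0, cavity = FALSE,
                      scope_length = scope_length, portal = c(0, 0, -30),
                      texture_contrast = 0.1)
  make_scene(cfg, seed = seed)
}

# gently bumped default-size scene but cheap (fewer frames)
small_scene <- function(seed = 1, n_frames = 20, width = 32, height = 32) {
  cfg <- scene_config(n_frames = n_frames, width = width, height = height,
                      keyframe_stride = 4)
  make_scene(cfg, seed = seed)
}

# a well-conditioned cloud: plane-ish sheet of anisotropic gaussians with
# distinct depths (depth ties make compositing non-differentiable)
sheet_cloud <- function(n_side = 8, z0 = 10, opacity = 0.85, seed = 42,
                        spread = 2.5) {
  set.seed(seed)
  g <- as.matrix(expand.grid(x = seq(-spread, spread, length.out = n_side),
                             y = seq(-spread, spread, length.out = n_side)))
  N <- n_side^2
  pos <- cbind(g, z0 + 0.3 * sin(g[, 1]) + 0.05 * g[, 2]^2 +
                 0.03 * rnorm(N))
  gaussian_cloud(
    pos,
    cbind(log(0.45) + rnorm(N, 0, 0.1), log(0.5) + rnorm(N, 0, 0.1),
          log(0.12) + rnorm(N, 0, 0.1)),
    cbind(1, 0.05 * rnorm(N), 0.05 * rnorm(N), 0.05 * rnorm(N)),
    rep(log(opacity / (1 - opacity)), N) + rnorm(N, 0, 0.2),
    matrix(runif(N * 3, 0.3, 0.8), N, 3))
}

random_cloud <- function(n = 30, seed = 1, zrange = c(5, 20)) {
  set.seed(seed)
  gaussian_cloud(cbind(runif(n, -4, 4), runif(n, -4, 4),
                       runif(n, zrange[1], zrange[2])),
                 matrix(log(runif(n * 3, 0.1, 0.8)), n, 3),
                 matrix(rnorm(n * 4), n, 4),
                 rnorm(n, 0, 2),
                 matrix(runif(n * 3), n, 3))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}

# study-scale fixture: the default synthetic scene (64x64, 20 keyframes,
# 2000 initial Gaussians) trained for 1500 iterations with and without depth
# supervision; built once and cached for the session
study_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- make_scene(scene_config(), seed = 0)
    kfs <- scene_keyframes(sc, seed = 0)
    prior <- simulate_sparse_prior(sc, seed = 0)
    rec <- recover_sequence(prior, kfs$frames)
    frames <- arthrosplat:::attach_pseudo_maps(kfs$frames, rec)
    cloud0 <- init_from_points(prior$points, prior$colors)
    cfg <- train_config(seed = 0)
    fit_d <- train_gaussians(cloud0, frames, loss_weights(), cfg)
    fit_0 <- train_gaussians(cloud0, frames, loss_weights(lambda_d = 0), cfg)
    gtpts <- sample_mesh(scene_mesh(sc), 50000, seed = 2)
    cache <<- list(scene = sc, frames = frames, prior = prior,
                   cloud_d = fit_d$cloud, cloud_0 = fit_0$cloud,
                   gt_points = gtpts)
    cache
  }
})

# plain per-pixel SSIM oracle (valid region, 11x11 gaussian window)
ssim_oracle <- function(x, y) {
  k1 <- exp(-((1:11) - 6)^2 / (2 * 1.5^2)); k1 <- k1 / sum(k1)
  K2 <- outer(k1, k1)
  H <- nrow(x); W <- ncol(x)
  C1 <- 1e-4; C2 <- 9e-4
  vals <- c()
  for (i in 1:(H - 10)) for (j in 1:(W - 10)) {
    wx <- x[i:(i + 10), j:(j + 10)]; wy <- y[i:(i + 10), j:(j + 10)]
    mx <- sum(K2 * wx); my <- sum(K2 * wy)
    vx <- sum(K2 * wx^2) - mx^2; vy <- sum(K2 * wy^2) - my^2
    vxy <- sum(K2 * wx * wy) - mx * my
    vals <- c(vals, (2 * mx * my + C1) * (2 * vxy + C2) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

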