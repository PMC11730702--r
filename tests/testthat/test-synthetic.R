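test_that("scene generation is bit-identical for the same (config, seed)", {
  cfg <- scene_config(n_frames = 12, width = 24, height = 24)
  s1 <- make_scene(cfg, seed = 5)
  s2 <- make_scene(cfg, seed = 5)
  expect_identical(s1$bumps, s2$bumps)
  expect_identical(s1$texture, s2$texture)
  expect_identical(s1$true_affine, s2$true_affine)
  expect_identical(lapply(s1$trajectory, unclass),
                   lapply(s2$trajectory, unclass))
  g1 <- render_ground_truth(s1, 3); g2 <- render_ground_truth(s2, 3)
  expect_identical(g1$image, g2$image)
  s3 <- make_scene(cfg, seed = 6)
  expect_false(identical(s1$bumps, s3$bumps))
})

test_that("pivoting trajectories keep the camera on a sphere about the portal", {
  cfg <- scene_config(motion = "pivoting", n_frames = 30, width = 24,
                      height = 24)
  sc <- make_scene(cfg, seed = 1)
  centers <- t(vapply(sc$trajectory, camera_center, numeric(3)))
  r <- sqrt(rowSums(sweep(centers, 2, cfg$portal)^2))
  expect_lt(max(abs(r - cfg$scope_length)), 1e-6)
})

test_that("the surface fills at least half of every default-scene view", {
  sc <- make_scene(scene_config(n_frames = 10), seed = 0)
  for (i in seq_along(sc$trajectory)) {
    gt <- render_ground_truth(sc, i)
    expect_gte(mean(gt$hit), 0.5)
  }
})

test_that("a fronto-parallel plane renders constant depth equal to distance", {
  sc <- plane_scene(seed = 2, width = 32, height = 32)
  gt <- render_ground_truth(sc, 1)
  expect_true(all(gt$hit))
  cc <- camera_center(sc$trajectory[[1]])
  expect_lt(max(abs(gt$depth + cc[3])), 1e-6)  # plane z = 0, camera at z < 0
})

test_that("central-ray depth matches a 1-D root-finding oracle", {
  sc <- small_scene(seed = 7)
  p <- sc$trajectory[[1]]
  cc <- camera_center(p)
  K <- sc$intrinsics
  gt <- render_ground_truth(sc, 1)
  # oracle: uniroot on g(t) = z(t) - f(x(t), y(t)) along the central ray
  dcam <- c((K$cx - K$cx) / K$fx, (K$cy - K$cy) / K$fy, 1)
  dw <- as.numeric(t(p$R) %*% dcam)
  g <- function(t) {
    q <- cc + t * dw
    q[3] - arthrosplat:::heightfield_eval_cpp(sc$bumps, q[1], q[2])$z
  }
  t_star <- uniroot(g, c(1, 60), tol = 1e-12)$root
  # central pixel: cx, cy sit between the two middle pixels; use bilinear
  d_center <- bilinear_sample(gt$depth, cbind(K$cx, K$cy))
  # compare against the analytic value at the *pixel* closest to center
  v <- round(K$cy) + 1; u <- round(K$cx) + 1
  dpix <- c((u - 1 - K$cx) / K$fx, (v - 1 - K$cy) / K$fy, 1)
  dwp <- as.numeric(t(p$R) %*% dpix)
  gp <- function(t) {
    q <- cc + t * dwp
    q[3] - arthrosplat:::heightfield_eval_cpp(sc$bumps, q[1], q[2])$z
  }
  tp <- uniroot(gp, c(1, 60), tol = 1e-12)$root
  expect_lt(abs(gt$depth[v, u] - tp), 1e-6)
  expect_lt(abs(d_center - t_star), 0.05)  # bilinear vs analytic: small
})

test_that("translating the camera toward a plane shifts all depths by delta", {
  sc <- plane_scene(seed = 3, width = 24, height = 24)
  g1 <- render_ground_truth(sc, 1)
  delta <- 2.5
  p <- sc$trajectory[[1]]
  cc <- camera_center(p) + delta * t(p$R)[, 3]  # move along the optical axis
  sc$trajectory[[1]] <- pose(p$R, -as.numeric(p$R %*% cc))
  g2 <- render_ground_truth(sc, 1)
  expect_lt(max(abs((g1$depth - g2$depth) - delta)), 1e-6)
})

test_that("disparity simulation: exact affine inverse, determinism, noise", {
  sc <- small_scene(seed = 4)  # bumpy surface: non-constant depth
  gt <- render_ground_truth(sc, 2)
  d0 <- simulate_disparity(gt$depth, A_true = 7, B_true = 2, noise_sigma = 0,
                           seed = 1)
  expect_false(attr(d0, "degenerate"))
  # noiseless: fitting (A, B) on the normalized map reconstructs depth exactly
  hit <- gt$depth > 0
  fit <- stats::lm.fit(cbind(d0[hit], 1), gt$depth[hit])$coefficients
  expect_lt(abs(fit[1] - attr(d0, "A_eff")), 1e-9)
  expect_lt(abs(fit[2] - attr(d0, "B_eff")), 1e-9)
  recon <- attr(d0, "A_eff") * d0[hit] + attr(d0, "B_eff")
  expect_lt(max(abs(recon - gt$depth[hit])), 1e-9)
  # same seed, same noise
  dn1 <- simulate_disparity(gt$depth, 7, 2, noise_sigma = 0.005, seed = 9)
  dn2 <- simulate_disparity(gt$depth, 7, 2, noise_sigma = 0.005, seed = 9)
  expect_identical(as.vector(dn1), as.vector(dn2))
  expect_false(identical(
    as.vector(simulate_disparity(gt$depth, 7, 2, 0.005, seed = 10)),
    as.vector(dn1)))
  # noisy map: fitted (A, B) on 200 pixels lands within 3 standard errors
  # of the recorded effective truth (closed-form least-squares covariance)
  set.seed(2)
  px <- sample(which(hit), 200)
  x <- dn1[px]; z <- gt$depth[px]
  X <- cbind(x, 1)
  beta <- solve(crossprod(X), crossprod(X, z))
  res <- z - X %*% beta
  covb <- solve(crossprod(X)) * sum(res^2) / (200 - 2)
  se <- sqrt(diag(covb))
  expect_lt(abs(beta[1] - attr(dn1, "A_eff")), 3 * se[1] + 1e-9)
  expect_lt(abs(beta[2] - attr(dn1, "B_eff")), 3 * se[2] + 1e-9)
  # constant depth map degenerates gracefully
  dd <- suppressWarnings(simulate_disparity(matrix(5, 4, 4), 2, 1, 0, 1))
  expect_true(attr(dd, "degenerate"))
  expect_true(all(dd == 0.5))
})

test_that("sparse prior: exact reprojection at zero noise, full visibility", {
  sc <- small_scene(seed = 8)
  prior <- simulate_sparse_prior(sc, n_points = 100, pixel_noise_sd = 0,
                                 depth_noise_rel = 0, seed = 8)
  expect_equal(nrow(prior$points), 100)
  # every stored point is observed in at least one keyframe
  expect_true(all(seq_len(100) %in% prior$observations$point))
  # zero noise: stored points reproject exactly onto their observations
  for (f in unique(prior$observations$frame)[1:3]) {
    obs <- prior$observations[prior$observations$frame == f, ]
    j <- which(sc$keyframes == f)
    pr <- project_points(prior$points[obs$point, , drop = FALSE],
                         sc$trajectory[[f]], sc$intrinsics)
    expect_lt(max(abs(pr$uv - cbind(obs$u, obs$v))), 1e-9)
  }
  expect_error(simulate_sparse_prior(sc, n_points = 5), ">= 10")
  expect_error(simulate_sparse_prior(sc, n_points = 1e7), "exceeds")
})

test_that("sparse prior reprojection error tracks the pixel noise level", {
  sc <- small_scene(seed = 9)
  sdpix <- 0.8
  prior <- simulate_sparse_prior(sc, n_points = 500, pixel_noise_sd = sdpix,
                                 depth_noise_rel = 0, seed = 9)
  errs <- c()
  for (f in unique(prior$observations$frame)) {
    obs <- prior$observations[prior$observations$frame == f, ]
    pr <- project_points(prior$true_points[obs$point, , drop = FALSE],
                         sc$trajectory[[f]], sc$intrinsics)
    errs <- c(errs, pr$uv - cbind(obs$u, obs$v))
  }
  rmse <- sqrt(mean(errs^2))
  expect_lt(abs(rmse - sdpix) / sdpix, 0.2)
})

test_that("region masks partition the hit mask and are pairwise disjoint", {
  sc <- small_scene(seed = 10)
  f <- sc$keyframes[2]
  gt <- render_ground_truth(sc, f)
  nlab <- nrow(sc$region_seeds) + as.integer(!is.null(sc$cavity))
  masks <- lapply(seq_len(nlab), function(l)
    suppressWarnings(simulate_mask(sc, l, f)))
  un <- Reduce(`|`, masks)
  expect_identical(un, gt$hit)
  for (a in 1:(nlab - 1)) for (b in (a + 1):nlab)
    expect_false(any(masks[[a]] & masks[[b]]))
  expect_warning(simulate_mask(sc, 99L, f), "absent")
})

test_that("a disk region on a plane projects to its analytic pixel area", {
  sc <- plane_scene(seed = 11, width = 64, height = 64, scope_length = 16)
  # inject a negligible-depth cavity so its label contour is an exact disk
  sigma <- 2
  sc$cavity <- c(0, 0, sigma, 0.01)
  sc$bumps <- rbind(sc$bumps, sc$cavity)
  lab <- nrow(sc$region_seeds) + 1L
  m <- simulate_mask(sc, lab, 1)
  d <- -camera_center(sc$trajectory[[1]])[3]  # plane at z = 0
  r_mm <- sigma * sqrt(2 * log(2))            # half-depth contour radius
  area_px <- pi * (sc$intrinsics$fx * r_mm / d)^2
  expect_lt(abs(sum(m) - area_px) / area_px, 0.05)
})

test_that("noiseless generator self-consistency: disparity round trip to 3D", {
  sc <- small_scene(seed = 12)
  kfs <- scene_keyframes(sc, seed = 12, disparity_noise = 0)
  fr <- kfs$frames[[1]]
  j <- 1
  pd <- to_pseudo_depth(fr$disparity,
                        list(A = kfs$effective_affine$A_eff[j],
                             B = kfs$effective_affine$B_eff[j]))
  hit <- fr$gt_depth > 0
  expect_lt(max(abs(pd[hit] - fr$gt_depth[hit])), 1e-6)
})
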