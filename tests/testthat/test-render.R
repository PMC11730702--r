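test_that("init_from_points: counts, grid scale = spacing, duplicate guard", {
  set.seed(1)
  pts <- matrix(rnorm(45), 15, 3)
  cl <- init_from_points(pts)
  expect_equal(n_gaussians(cl), 15)
  expect_equal(unname(opacities(cl)), rep(0.1, 15), tolerance = 1e-12)
  # regular grid with spacing h: brute-force 3-NN oracle; interior points
  # have all three nearest neighbours at exactly h
  h <- 0.7
  g <- as.matrix(expand.grid(x = h * (1:5), y = h * (1:5), z = 0))
  clg <- init_from_points(g)
  oracle <- vapply(seq_len(nrow(g)), function(i) {
    d <- sort(sqrt(colSums((t(g) - g[i, ])^2)))[2:4]  # skip self
    mean(d)
  }, 0)
  expect_lt(max(abs(scales(clg)[, 1] - oracle)), 1e-9)
  interior <- g[, 1] > h & g[, 1] < 5 * h & g[, 2] > h & g[, 2] < 5 * h
  expect_lt(max(abs(scales(clg)[interior, ] - h)), 1e-9)
  # duplicates: floored scale, no NaN
  dup <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  cld <- init_from_points(dup, min_scale = 1e-4)
  expect_true(all(is.finite(cld$log_scales)))
  expect_true(all(scales(cld) >= 1e-4))
  expect_error(init_from_points(matrix(0, 0, 3)), "empty")
})

test_that("a single opaque on-axis Gaussian peaks at the principal point", {
  K <- tiny_intrinsics(16, 16, 40)
  cl <- gaussian_cloud(c(0.12, -0.08, 5), rep(log(0.5), 3), c(1, 0, 0, 0),
                       arthrosplat:::logit(0.999), c(1, 0, 0))
  # slight off-axis: peak alpha at the projection
  out <- render_gaussians(cl, pose(), K)
  pr <- project_points(cl$positions, pose(), K)
  pk <- which(out$alpha == max(out$alpha), arr.ind = TRUE)
  expect_lt(abs(pk[1, 2] - 1 - pr$uv[1]), 1)   # column = u
  expect_lt(abs(pk[1, 1] - 1 - pr$uv[2]), 1)   # row = v
  expect_lt(abs(out$depth[pk[1, 1], pk[1, 2]] - 5), 1e-3)
  # near-opaque: peak alpha approaches the opacity (clamped at 0.99)
  expect_gt(max(out$alpha), 0.98)
})

test_that("a cloud behind the camera renders pure background with zero alpha", {
  K <- tiny_intrinsics()
  cl <- gaussian_cloud(rbind(c(0, 0, -5), c(1, 1, -2)),
                       matrix(log(0.5), 2, 3),
                       rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                       c(3, 3), matrix(0.5, 2, 3))
  out <- render_gaussians(cl, pose(), K, bg = c(0.2, 0.3, 0.4))
  expect_true(all(out$alpha == 0))
  expect_equal(unique(as.vector(out$image[, , 1])), 0.2)
  expect_equal(unique(as.vector(out$image[, , 3])), 0.4)
})

test_that("two Gaussians on one ray composite by the closed two-term formula", {
  K <- tiny_intrinsics(16, 16, 40)
  o1 <- 0.95; o2 <- 0.9
  # scales wide enough that the Gaussian falloff is flat at the center pixel
  cl <- gaussian_cloud(rbind(c(0, 0, 5), c(0, 0, 10)),
                       matrix(log(c(1, 1, 1, 2, 2, 2)), 2, 3, byrow = TRUE),
                       rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                       arthrosplat:::logit(c(o1, o2)),
                       rbind(c(1, 0, 0), c(0, 1, 0)))
  out <- render_gaussians(cl, pose(), K)
  cpx <- c(8, 8)  # center pixel (cx = cy = 7.5 -> between 8 and 9, 1-based)
  # at the shared projection: w1 = a1, w2 = (1 - a1) a2 with a_i ~ o_i
  r <- out$image[cpx[1], cpx[2], 1]
  g <- out$image[cpx[1], cpx[2], 2]
  expect_lt(abs(r - o1), 1e-2)
  expect_lt(abs(g - (1 - o1) * o2), 2e-2)
  # removing the near-opaque front one reveals the back color
  cl2 <- arthrosplat:::subset_cloud(cl, 2)
  out2 <- render_gaussians(cl2, pose(), K)
  expect_gt(out2$image[cpx[1], cpx[2], 2], 0.85)
  expect_lt(out2$image[cpx[1], cpx[2], 1], 1e-9)
})

test_that("per-pixel compositing weights never exceed 1 on random clouds", {
  K <- tiny_intrinsics(12, 12, 25)
  for (s in 1:100) {
    cl <- random_cloud(n = 25, seed = s)
    out <- render_gaussians(cl, pose(), K)
    expect_lte(max(out$alpha), 1 + 1e-12)
    expect_gte(min(out$alpha), 0)
  }
})

test_that("rendered normals are unit-norm where alpha is positive", {
  K <- tiny_intrinsics()
  out <- render_gaussians(sheet_cloud(), pose(), K)
  n <- out$normal
  nn <- sqrt(n[, , 1]^2 + n[, , 2]^2 + n[, , 3]^2)
  expect_lt(max(abs(nn[out$alpha > 1e-6] - 1)), 1e-9)
})

test_that("export_point_cloud thresholds opacity exactly", {
  cl <- random_cloud(n = 40, seed = 2)
  expect_equal(nrow(export_point_cloud(cl, threshold = 0)), 40)
  expect_equal(nrow(export_point_cloud(cl, threshold = 1)), 0)
  thr <- 0.5
  oracle <- sum(opacities(cl) >= thr)
  expect_equal(nrow(export_point_cloud(cl, thr)), oracle)
})

test_that("analytic gradients match finite differences on a 16x16 render", {
  K <- tiny_intrinsics(16, 16, 40)
  cloud <- sheet_cloud()
  set.seed(10)
  target <- array(runif(16 * 16 * 3, 0.3, 0.7), c(16, 16, 3))
  pd <- matrix(10.3, 16, 16) + matrix(rnorm(256, 0, 0.1), 16)
  pn <- array(0, c(16, 16, 3)); pn[, , 3] <- -1
  w <- loss_weights()
  gr <- arthrosplat:::total_loss_grad(cloud, pose(), K, target, pd, pn, w)
  f <- function(cl) arthrosplat:::total_loss_value(cl, pose(), K, target, pd,
                                                   pn, w)
  set.seed(11)
  N <- n_gaussians(cloud)
  for (p in c("positions", "log_scales", "opacity_logits", "colors")) {
    for (trial in 1:6) {
      i <- sample(N, 1)
      j <- if (p == "opacity_logits") NULL else sample(ncol(cloud[[p]]), 1)
      eps <- 1e-5
      c1 <- cloud; c2 <- cloud
      if (is.null(j)) {
        c1[[p]][i] <- c1[[p]][i] + eps; c2[[p]][i] <- c2[[p]][i] - eps
        an <- gr$grads[[p]][i]
      } else {
        c1[[p]][i, j] <- c1[[p]][i, j] + eps
        c2[[p]][i, j] <- c2[[p]][i, j] - eps
        an <- gr$grads[[p]][i, j]
      }
      fd <- (f(c1) - f(c2)) / (2 * eps)
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-3)
    }
  }
})
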