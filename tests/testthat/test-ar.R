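# a dense opaque plane-of-gaussians scene the AR tools can operate on
ar_fixture <- function() {
  K <- tiny_intrinsics(32, 32, 40)
  g <- as.matrix(expand.grid(x = seq(-4.5, 4.5, length.out = 15),
                             y = seq(-4.5, 4.5, length.out = 15)))
  N <- nrow(g)
  set.seed(20)
  pos <- cbind(g, 10 + 0.001 * rnorm(N))  # flat sheet, distinct depths
  cloud <- gaussian_cloud(pos, matrix(log(0.45), N, 3),
                          matrix(rep(c(1, 0, 0, 0), each = N), N, 4),
                          rep(arthrosplat:::logit(0.95), N),
                          matrix(0.6, N, 3))
  list(K = K, cloud = cloud, view = pose())
}

test_that("picking at a lone Gaussian's projection returns its center (k=1)", {
  K <- tiny_intrinsics(16, 16, 40)
  cl <- gaussian_cloud(c(0.5, -0.3, 8), rep(log(0.6), 3), c(1, 0, 0, 0),
                       arthrosplat:::logit(0.95), c(1, 1, 1))
  pr <- project_points(cl$positions, pose(), K)
  pk <- pick_point(cl, pose(), K, round(pr$uv), k = 1)
  expect_equal(as.numeric(pk$world_point), as.numeric(cl$positions))
  expect_equal(pk$contributing_gaussians, 1L)
})

test_that("k equal to the cloud size averages all opaque centers", {
  fx <- ar_fixture()
  pk <- pick_point(fx$cloud, fx$view, fx$K, c(15.5, 15.5),
                   k = n_gaussians(fx$cloud))
  expect_lt(max(abs(pk$world_point - colMeans(fx$cloud$positions))), 1e-12)
})

test_that("picking demands surface coverage (alpha > 0.5) and valid pixels", {
  K <- tiny_intrinsics(16, 16, 40)
  cl <- gaussian_cloud(c(0, 0, 8), rep(log(0.3), 3), c(1, 0, 0, 0),
                       arthrosplat:::logit(0.9), c(1, 1, 1))
  expect_error(pick_point(cl, pose(), K, c(1, 1)), "alpha")
  expect_error(pick_point(cl, pose(), K, c(40, 2)), "outside")
})

test_that("measurement is symmetric, zero at identical pixels, near-analytic", {
  fx <- ar_fixture()
  r <- render_gaussians(fx$cloud, fx$view, fx$K)
  d0 <- measure_distance(fx$cloud, fx$view, fx$K, c(10, 10), c(10, 10),
                         render = r)
  expect_equal(as.numeric(d0), 0)
  dab <- measure_distance(fx$cloud, fx$view, fx$K, c(8, 15), c(24, 17),
                          render = r)
  dba <- measure_distance(fx$cloud, fx$view, fx$K, c(24, 17), c(8, 15),
                          render = r)
  expect_identical(as.numeric(dab), as.numeric(dba))
  # analytic chord on the plane z = 10
  pa <- unproject_pixels(c(8, 15), 10, fx$view, fx$K)
  pb <- unproject_pixels(c(24, 17), 10, fx$view, fx$K)
  expect_lt(abs(dab - sqrt(sum((pa - pb)^2))) / sqrt(sum((pa - pb)^2)), 0.05)
})

test_that("a full-image mask anchors all visible opaque Gaussians", {
  fx <- ar_fixture()
  mask <- matrix(TRUE, 32, 32)
  anc <- anchor_annotation(fx$cloud, fx$view, fx$K, mask)
  pr <- project_points(fx$cloud$positions, fx$view, fx$K)
  visible <- which(pr$valid & pr$uv[, 1] >= -0.5 & pr$uv[, 1] <= 31.5 &
                     pr$uv[, 2] >= -0.5 & pr$uv[, 2] <= 31.5)
  expect_setequal(anc$gaussian_indices, visible)
})

test_that("an empty mask yields an empty anchor and an unchanged render", {
  fx <- ar_fixture()
  expect_warning(anc <- anchor_annotation(fx$cloud, fx$view, fx$K,
                                          matrix(FALSE, 32, 32)), "empty")
  expect_length(anc$gaussian_indices, 0)
  ra <- render_annotation(fx$cloud, anc, fx$view, fx$K)
  base <- render_gaussians(fx$cloud, fx$view, fx$K)
  expect_identical(ra$image, base$image)
  expect_false(any(ra$mask))
})

test_that("anchored and unanchored weight shares partition the alpha", {
  fx <- ar_fixture()
  set.seed(21)
  fl <- runif(n_gaussians(fx$cloud)) < 0.4
  r1 <- render_gaussians(fx$cloud, fx$view, fx$K, flag = fl)
  r2 <- render_gaussians(fx$cloud, fx$view, fx$K, flag = !fl)
  expect_lt(max(abs(r1$flag_weight + r2$flag_weight - r1$alpha)), 1e-9)
})

test_that("the depth gate excludes occluded background Gaussians", {
  K <- tiny_intrinsics(32, 32, 40)
  # front sheet at z = 8 over a background sheet at z = 16
  g <- as.matrix(expand.grid(x = seq(-3, 3, length.out = 10),
                             y = seq(-3, 3, length.out = 10)))
  N <- nrow(g)
  set.seed(22)
  mk <- function(z) cbind(g, z + 0.001 * rnorm(N))
  cloud <- gaussian_cloud(rbind(mk(8), mk(16)),
                          matrix(log(0.4), 2 * N, 3),
                          matrix(rep(c(1, 0, 0, 0), each = 2 * N), 2 * N, 4),
                          rep(arthrosplat:::logit(0.95), 2 * N),
                          matrix(0.5, 2 * N, 3))
  anc <- anchor_annotation(cloud, pose(), K, matrix(TRUE, 32, 32),
                           depth_tolerance = 1)
  expect_true(all(anc$gaussian_indices <= N))  # only the front sheet
})

test_that("landmark anchoring equals a brute-force radius filter", {
  fx <- ar_fixture()
  pk <- pick_point(fx$cloud, fx$view, fx$K, c(15, 15), k = 4)
  r <- 1.2
  lm <- anchor_landmark(fx$cloud, pk, radius = r)
  oracle <- which(sqrt(colSums((t(fx$cloud$positions) -
                                  pk$world_point)^2)) <= r)
  expect_setequal(lm$anchor$gaussian_indices, oracle)
  # radius covering everything selects the whole cloud
  lm_all <- anchor_landmark(fx$cloud, pk, radius = 1e6)
  expect_length(lm_all$anchor$gaussian_indices, n_gaussians(fx$cloud))
  # radius 0: a decorative Gaussian is inserted and flagged non-optimizable
  lm0 <- anchor_landmark(fx$cloud, pk, radius = 0)
  expect_equal(n_gaussians(lm0$cloud), n_gaussians(fx$cloud) + 1)
  expect_equal(lm0$anchor$gaussian_indices, n_gaussians(lm0$cloud))
  expect_true(tail(attr(lm0$cloud, "fixed"), 1))
  expect_lt(max(abs(lm0$cloud$positions[n_gaussians(lm0$cloud), ] -
                      pk$world_point)), 1e-12)
})

test_that("annotation re-rendering highlights and reproduces a block mask", {
  fx <- ar_fixture()
  mask <- matrix(FALSE, 32, 32); mask[8:24, 8:24] <- TRUE
  anc <- anchor_annotation(fx$cloud, fx$view, fx$K, mask,
                           highlight_color = c(0, 1, 0))
  ra <- render_annotation(fx$cloud, anc, fx$view, fx$K)
  expect_gt(miou(ra$mask, mask), 0.7)
  # highlighted pixels turn green
  expect_gt(mean(ra$image[, , 2][ra$mask]), mean(ra$image[, , 1][ra$mask]))
})
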