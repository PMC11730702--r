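test_that("psnr: identical images, exact 20 dB case, monotone in noise", {
  set.seed(1)
  I <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(psnr(I, I), Inf)
  J <- pmin(I + 0.1, Inf)  # uniform |difference| = 0.1
  expect_equal(psnr(J, I), 20, tolerance = 1e-12)
  sds <- c(0.01, 0.05, 0.2)
  ps <- vapply(sds, function(s) {
    set.seed(99)
    psnr(I + array(rnorm(length(I), 0, s), dim(I)), I)
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("ssim: identity, symmetry, brute-force oracle, negative structure", {
  set.seed(2)
  x <- matrix(runif(16 * 16), 16, 16)
  y <- matrix(runif(16 * 16), 16, 16)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-15)
  expect_equal(ssim(x, y), ssim_oracle(x, y), tolerance = 1e-9)
  # checkerboard against its negative: structure term flips sign
  cb <- 0.5 + 0.4 * outer(1:32, 1:32, function(i, j) (-1)^(i + j))
  expect_lt(ssim(1 - cb, cb), 0.5)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("ssim gradient matches finite differences", {
  set.seed(3)
  x <- matrix(runif(14 * 14), 14, 14)
  y <- matrix(runif(14 * 14), 14, 14)
  sg <- arthrosplat:::ssim_with_grad(x, y)
  expect_equal(sg$value, ssim(x, y))
  eps <- 1e-6
  for (idx in list(c(1, 1), c(7, 7), c(14, 3))) {
    x1 <- x; x1[idx[1], idx[2]] <- x1[idx[1], idx[2]] + eps
    x2 <- x; x2[idx[1], idx[2]] <- x2[idx[1], idx[2]] - eps
    fd <- (ssim(x1, y) - ssim(x2, y)) / (2 * eps)
    expect_lt(abs(fd - sg$grad[idx[1], idx[2]]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("miou: identities, disjoint, exact half-overlap third", {
  a <- matrix(FALSE, 10, 10); a[1:4, 1:10] <- TRUE
  expect_equal(miou(a, a), 1)
  b <- matrix(FALSE, 10, 10); b[6:9, 1:10] <- TRUE
  expect_equal(miou(a, b), 0)
  # equal rectangles overlapping by half: |I| = A/2, |U| = 3A/2 -> 1/3
  r1 <- matrix(FALSE, 10, 10); r1[1:4, 1:4] <- TRUE
  r2 <- matrix(FALSE, 10, 10); r2[1:4, 3:6] <- TRUE
  expect_equal(miou(r1, r2), 1 / 3)
  # both empty counts as perfect agreement
  e <- matrix(FALSE, 10, 10)
  expect_equal(miou(list(a, e), list(a, e)), 1)
})

test_that("rmse and hausdorff match brute-force O(n^2) oracles", {
  set.seed(4)
  A <- matrix(rnorm(60), 20, 3)
  B <- matrix(rnorm(45), 15, 3)
  d2 <- function(p, Q) min(sqrt(colSums((t(Q) - p)^2)))
  dAB <- apply(A, 1, d2, Q = B)
  dBA <- apply(B, 1, d2, Q = A)
  expect_equal(rmse_point_to_point(A, B), sqrt(mean(dAB^2)),
               tolerance = 1e-12)
  expect_equal(hausdorff_distance(A, B), max(max(dAB), max(dBA)),
               tolerance = 1e-12)
  expect_equal(rmse_point_to_point(A, A), 0)
  expect_equal(hausdorff_distance(A, A), 0)
  # hand case: 3-4-5 asymmetry, directed B->A dominates
  a1 <- matrix(0, 1, 3)
  b2 <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(hausdorff_distance(a1, b2), 5)
  # offset clouds with far-separated points: constant-offset rmse
  C <- matrix(c(0, 0, 0, 100, 0, 0, 0, 100, 0), 3, 3, byrow = TRUE)
  expect_equal(rmse_point_to_point(sweep(C, 2, c(1, 0, 0), "+"), C), 1)
  # max dominates mean
  expect_gte(hausdorff_distance(A, B), rmse_point_to_point(A, B))
})

test_that("mesh sampling: barycentric validity, area weighting, determinism", {
  tri <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
              faces = matrix(c(1, 2, 3), 1))
  s <- sample_mesh(tri, 500, seed = 1)
  expect_true(all(s[, 1] >= 0 & s[, 2] >= 0 & s[, 1] + s[, 2] <= 1 + 1e-12))
  expect_true(all(s[, 3] == 0))
  expect_identical(sample_mesh(tri, 50, seed = 7), sample_mesh(tri, 50, seed = 7))
  # two triangles with 9:1 area ratio
  two <- list(vertices = rbind(c(0, 0, 0), c(9, 0, 0), c(0, 2, 0),
                               c(10, 0, 0), c(12, 0, 0), c(10, 1, 0)),
              faces = rbind(c(1, 2, 3), c(4, 5, 6)))  # areas 9 and 1
  n <- 10000
  s <- sample_mesh(two, n, seed = 3)
  n_big <- sum(s[, 1] < 9.5)
  # binomial 99% bounds around p = 0.9
  expect_gt(n_big, qbinom(0.005, n, 0.9))
  expect_lt(n_big, qbinom(0.995, n, 0.9))
  expect_error(sample_mesh(list(vertices = tri$vertices,
                                faces = matrix(integer(0), 0, 3)), 10), "face")
})

test_that("similarity fit agrees with an independent Procrustes solution", {
  skip_if_not_installed("vegan")
  set.seed(5)
  X <- matrix(rnorm(90), 30, 3)
  R <- quat_to_rotmat(rnorm(4))
  Y <- 1.4 * X %*% t(R) + matrix(c(1, -2, 3), 30, 3, byrow = TRUE)
  fit <- arthrosplat:::similarity_fit(X, Y)
  pr <- vegan::procrustes(Y, X)  # rotates/scales X onto Y
  expect_equal(fit$scale, pr$scale, tolerance = 1e-9)
  expect_lt(max(abs(arthrosplat:::apply_similarity(X, fit$scale, fit$R,
                                                   fit$t) - Y)), 1e-9)
})

test_that("similarity ICP recovers a known transform and descends monotonically", {
  set.seed(6)
  X <- matrix(rnorm(300), 100, 3)
  R <- quat_to_rotmat(c(0.9, 0.2, -0.3, 0.1))
  Y <- 1.7 * X %*% t(R) + matrix(c(2, 1, -3), 100, 3, byrow = TRUE)
  al <- align_icp(X, Y)
  expect_lt(abs(al$scale - 1.7), 1e-4)
  expect_lt(max(abs(al$rotation - R)), 1e-4)
  expect_lt(max(abs(al$translation - c(2, 1, -3))), 1e-4)
  expect_lt(al$rmse_after, 1e-6)
  expect_true(all(diff(al$rmse_trace) <= 1e-12))
  # identical clouds: identity transform
  al2 <- align_icp(X, X)
  expect_lt(abs(al2$scale - 1), 1e-9)
  expect_lt(max(abs(al2$rotation - diag(3))), 1e-7)
  expect_lt(al2$rmse_after, 1e-9)
})
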