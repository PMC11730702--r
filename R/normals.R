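# Depth -> normal conversion: backproject every pixel to a camera-space point,
# take finite-difference tangents of the point map, and normalize their cross
# product, oriented toward the camera. This is the geometric core of
# depth-to-normal translators; it is deterministic and dependency-free.

# shift a matrix by (dv, du) with zero padding (dv > 0 pulls from below)
shift_mat <- function(M, dv, du) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(0, H, W)
  vs <- max(1, 1 + dv):min(H, H + dv)
  us <- max(1, 1 + du):min(W, W + du)
  out[vs - dv, us - du] <- M[vs, us]
  out
}

# Per-direction finite-difference stencil coefficients given a validity mask.
# Central difference where both neighbours are valid; one-sided only at the
# image border; pixels adjacent to an in-image invalid pixel (a depth hole)
# get no derivative and are dropped from the valid set. Returns coefficient
# matrices for offsets (+1, 0, -1) along the given axis plus the mask of
# pixels where the derivative exists.
.diff_stencil <- function(valid, axis) {
  H <- nrow(valid); W <- ncol(valid)
  if (axis == "u") {
    vp <- shift_mat(valid + 0, 0, 1) > 0   # neighbour at u+1 valid
    vm <- shift_mat(valid + 0, 0, -1) > 0  # neighbour at u-1 valid
    inb_p <- col(valid) < W                # neighbour +1 inside the image
    inb_m <- col(valid) > 1
  } else {
    vp <- shift_mat(valid + 0, 1, 0) > 0
    vm <- shift_mat(valid + 0, -1, 0) > 0
    inb_p <- row(valid) < H
    inb_m <- row(valid) > 1
  }
  central <- valid & vp & vm
  fwd <- valid & vp & !inb_m   # left/top border only
  bwd <- valid & vm & !inb_p   # right/bottom border only
  ok <- central | fwd | bwd
  cp <- 0.5 * central + 1 * fwd           # coefficient on neighbour +1
  c0 <- -1 * fwd + 1 * bwd                # coefficient on self
  cm <- -0.5 * central - 1 * bwd          # coefficient on neighbour -1
  list(cp = cp, c0 = c0, cm = cm, ok = ok)
}

# apply a stencil to one channel: d(q) = cp*M(q+1) + c0*M(q) + cm*M(q-1)
.stencil_apply <- function(M, st, axis) {
  if (axis == "u")
    st$cp * shift_mat(M, 0, 1) + st$c0 * M + st$cm * shift_mat(M, 0, -1)
  else
    st$cp * shift_mat(M, 1, 0) + st$c0 * M + st$cm * shift_mat(M, -1, 0)
}

# adjoint of .stencil_apply: scatter gbar back to the source pixels
.stencil_adjoint <- function(G, st, axis) {
  if (axis == "u")
    shift_mat(st$cp * G, 0, -1) + st$c0 * G + shift_mat(st$cm * G, 0, 1)
  else
    shift_mat(st$cp * G, -1, 0) + st$c0 * G + shift_mat(st$cm * G, 1, 0)
}

# internal: full forward state, reused by the VJP
.d2n_forward <- function(depth, intrinsics, valid = NULL) {
  H <- intrinsics$height; W <- intrinsics$width
  stopifnot(nrow(depth) == H, ncol(depth) == W)
  if (is.null(valid)) valid <- is.finite(depth) & depth > 0
  else valid <- valid & is.finite(depth) & depth > 0
  dirs <- pixel_ray_directions(intrinsics)
  d0 <- depth; d0[!valid] <- 0
  P <- array(0, c(H, W, 3))
  for (c in 1:3) P[, , c] <- d0 * dirs[, , c]
  su <- .diff_stencil(valid, "u")
  sv <- .diff_stencil(valid, "v")
  tu <- array(0, c(H, W, 3)); tv <- array(0, c(H, W, 3))
  for (c in 1:3) {
    tu[, , c] <- .stencil_apply(P[, , c], su, "u")
    tv[, , c] <- .stencil_apply(P[, , c], sv, "v")
  }
  cr <- array(0, c(H, W, 3))
  cr[, , 1] <- tu[, , 2] * tv[, , 3] - tu[, , 3] * tv[, , 2]
  cr[, , 2] <- tu[, , 3] * tv[, , 1] - tu[, , 1] * tv[, , 3]
  cr[, , 3] <- tu[, , 1] * tv[, , 2] - tu[, , 2] * tv[, , 1]
  nrm <- sqrt(cr[, , 1]^2 + cr[, , 2]^2 + cr[, , 3]^2)
  ok <- valid & su$ok & sv$ok & nrm > 1e-12
  # orient toward the camera: n . ray < 0
  dotdir <- cr[, , 1] * dirs[, , 1] + cr[, , 2] * dirs[, , 2] +
    cr[, , 3] * dirs[, , 3]
  sgn <- ifelse(dotdir > 0, -1, 1)
  normals <- array(0, c(H, W, 3))
  safe <- pmax(nrm, 1e-300)
  for (c in 1:3) {
    nc <- sgn * cr[, , c] / safe
    nc[!ok] <- 0
    normals[, , c] <- nc
  }
  list(normals = normals, valid = ok, cr = cr, nrm = nrm, sgn = sgn,
       tu = tu, tv = tv, su = su, sv = sv, dirs = dirs, in_valid = valid)
}

#' Convert a depth map to a unit normal map
#'
#' Backprojects each valid pixel to a camera-space point via the intrinsics,
#' computes tangent vectors by central finite differences of the point map
#' (one-sided at borders and next to invalid pixels), and returns the
#' normalized, camera-facing cross product. Pixels whose derivative stencil
#' touches invalid depth are marked invalid.
#'
#' @param depth H x W depth map (camera-frame z, length units); `NA` or
#'   non-positive entries are invalid.
#' @param intrinsics [camera_intrinsics()] matching the map size.
#' @param valid Optional H x W logical mask of additionally valid pixels.
#' @return A list of class `normal_map` with `normals` (H x W x 3 unit
#'   vectors, camera frame, zero where invalid) and `valid` (H x W logical).
#' @examples
#' K <- camera_intrinsics(40, 40, 15.5, 15.5, 32, 32)
#' nm <- depth_to_normal(matrix(5, 32, 32), K)
#' nm$normals[16, 16, ]  # fronto-parallel plane: (0, 0, -1)
#' @export
depth_to_normal <- function(depth, intrinsics, valid = NULL) {
  st <- .d2n_forward(depth, intrinsics, valid)
  structure(list(normals = st$normals, valid = st$valid), class = "normal_map")
}

# Vector-Jacobian product of depth_to_normal: given the adjoint g (H x W x 3)
# of the unit normal map, return dL/d(depth). Used to backpropagate the
# depth-normal consistency loss through the rendered depth.
depth_to_normal_vjp <- function(depth, intrinsics, g, valid = NULL) {
  st <- .d2n_forward(depth, intrinsics, valid)
  H <- intrinsics$height; W <- intrinsics$width
  ok <- st$valid
  nrm <- pmax(st$nrm, 1e-300)
  # n = sgn * cr / |cr|;  cbar = sgn*(g - n (n.g)) / |cr|
  n <- st$normals
  ndotg <- n[, , 1] * g[, , 1] + n[, , 2] * g[, , 2] + n[, , 3] * g[, , 3]
  cbar <- array(0, c(H, W, 3))
  for (c in 1:3) {
    v <- st$sgn * (g[, , c] - n[, , c] * ndotg) / nrm
    v[!ok] <- 0
    cbar[, , c] <- v
  }
  # cross product adjoints: tu_bar = tv x cbar, tv_bar = cbar x tu
  tu <- st$tu; tv <- st$tv
  tub <- array(0, c(H, W, 3)); tvb <- array(0, c(H, W, 3))
  tub[, , 1] <- tv[, , 2] * cbar[, , 3] - tv[, , 3] * cbar[, , 2]
  tub[, , 2] <- tv[, , 3] * cbar[, , 1] - tv[, , 1] * cbar[, , 3]
  tub[, , 3] <- tv[, , 1] * cbar[, , 2] - tv[, , 2] * cbar[, , 1]
  tvb[, , 1] <- cbar[, , 2] * tu[, , 3] - cbar[, , 3] * tu[, , 2]
  tvb[, , 2] <- cbar[, , 3] * tu[, , 1] - cbar[, , 1] * tu[, , 3]
  tvb[, , 3] <- cbar[, , 1] * tu[, , 2] - cbar[, , 2] * tu[, , 1]
  gd <- matrix(0, H, W)
  for (c in 1:3) {
    Pb <- .stencil_adjoint(tub[, , c], st$su, "u") +
      .stencil_adjoint(tvb[, , c], st$sv, "v")
    gd <- gd + Pb * st$dirs[, , c]
  }
  gd[!st$in_valid] <- 0
  gd
}

#' Per-pixel gradient magnitude of a normal map
#'
#' L1 norm of the forward finite-difference spatial gradients of the three
#' normal channels; zero wherever the pixel or a forward neighbour is
#' invalid. Used as the smoothness term of the normal-prior loss.
#'
#' @param normal_map A `normal_map` from [depth_to_normal()], or a plain
#'   H x W x 3 array (then all pixels are treated as valid).
#' @return H x W matrix of gradient magnitudes.
#' @export
normal_gradient <- function(normal_map) {
  if (inherits(normal_map, "normal_map")) {
    n <- normal_map$normals; valid <- normal_map$valid
  } else {
    n <- normal_map; valid <- matrix(TRUE, dim(n)[1], dim(n)[2])
  }
  H <- dim(n)[1]; W <- dim(n)[2]
  vu <- valid & shift_mat(valid + 0, 0, 1) > 0
  vv <- valid & shift_mat(valid + 0, 1, 0) > 0
  g <- matrix(0, H, W)
  for (c in 1:3) {
    du <- shift_mat(n[, , c], 0, 1) - n[, , c]
    dv <- shift_mat(n[, , c], 1, 0) - n[, , c]
    g <- g + abs(du) * vu + abs(dv) * vv
  }
  g
}

# Adjoint of mean(normal_gradient): returns dL/dn (H x W x 3) given the
# upstream scalar weight already folded in (gscale = lambda / n_pixels).
normal_gradient_vjp <- function(n, valid, gscale) {
  H <- dim(n)[1]; W <- dim(n)[2]
  vu <- valid & shift_mat(valid + 0, 0, 1) > 0
  vv <- valid & shift_mat(valid + 0, 1, 0) > 0
  g <- array(0, c(H, W, 3))
  for (c in 1:3) {
    du <- shift_mat(n[, , c], 0, 1) - n[, , c]
    dv <- shift_mat(n[, , c], 1, 0) - n[, , c]
    su <- sign(du) * vu * gscale
    sv <- sign(dv) * vv * gscale
    # d|du|/dn: +s at neighbour (u+1), -s at self
    g[, , c] <- -su - sv + shift_mat(su, 0, -1) + shift_mat(sv, -1, 0)
  }
  g
}
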