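---
title: "Reconstruction and AR guidance for monocular arthroscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction and AR guidance for monocular arthroscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Arthroscopic video is monocular, feature-scarce, and acquired through a
camera whose motion is constrained by the entry portal. A SLAM front end can
recover camera poses and a *sparse* 3D point map from such footage, and a
monocular depth network can produce dense per-frame *disparity* maps -- but
the disparity is only defined up to an unknown per-frame scale and shift,
and the sparse map is far too thin to support measurement or annotation.
`arthrosplat` implements the dense-reconstruction stage that bridges the
two, and the AR operators that a reconstructed scene enables:

1. **Scale recovery.** For every keyframe, 2D-3D correspondences between
   the tracked sparse points and the disparity map are used to fit the
   affine map `D_pseudo = A * d + B` by minimizing
   `sum (X_z - (A x_d + B))^2`, where `X_z` is the camera-frame depth of a
   sparse 3D point and `x_d` the disparity sampled at its observed pixel.
   The optimizer is Nelder-Mead started at the closed-form least-squares
   solution (see *Numerical choices*). The per-keyframe `(A, B)` pairs give
   metrically consistent pseudo-depth maps across the sequence.
2. **Pseudo-normals.** Depth maps are converted to camera-facing unit
   normal maps by backprojecting the pixel grid to a camera-space point
   map, taking finite-difference tangents, and normalizing their cross
   product (the geometric core of depth-to-normal translators).
3. **Surface-aligned Gaussian splatting.** An explicit 3D Gaussian cloud
   (positions, anisotropic log-scales, quaternions, opacity logits,
   degree-0 RGB) is initialized from the sparse points and optimized under

   `L = (1 - l_ssim) L1 + l_ssim L_D-SSIM + l_d L_d + l_o L_o + l_c L_c + l_n L_n`

   where `L_d = |D_hat - D_pseudo|_1` supervises rendered depth with the
   pseudo-depth, `L_c = 1 - N_hat . N(D_hat)` enforces depth-normal
   consistency, `L_n = l_1 (1 - N_hat . N_pseudo) + l_2 |grad N_hat|_1`
   regularizes the rendered normal toward the pseudo-normal and toward
   smoothness, and `L_o = exp(-(o - 0.5)^2 / 0.05)` (mean over Gaussians)
   pushes opacities toward binary to suppress translucent floaters.
4. **AR tools.** Point picking (unproject the rendered depth, average the
   `k` nearest opaque Gaussian centers), Euclidean measurement between two
   picks, and annotation anchoring: the Gaussians that generated a masked
   image region are selected (projected center inside the mask, camera
   depth within a tolerance of the rendered depth) and re-rendered with a
   highlight color from any viewpoint, yielding a predicted mask wherever
   the anchored subset carries more than half of the compositing weight.
5. **Evaluation.** Similarity (7-DoF) ICP alignment to a ground-truth
   surface, point-to-point RMSE and symmetric Hausdorff distance, PSNR and
   SSIM of re-rendered views, mask mIoU, and a randomized measurement-error
   study over 500 picked pixel pairs.

# The renderer

The CPU rasterizer follows the standard EWA splatting formulation. Each
Gaussian's world covariance `R(q) diag(s^2) R(q)'` is pushed through the
camera rotation and the perspective Jacobian at its mean; a `0.3 px^2`
isotropic dilation is added in screen space. Gaussians are sorted by camera
depth (stable sort, so ties are deterministic) and alpha-composited
front-to-back with per-pixel transmittance; compositing stops once the
transmittance falls below `1e-6`. Outputs are the RGB image over a
background color, the alpha-normalized expected depth `sum(w_i z_i) /
sum(w_i)`, the composited and renormalized per-Gaussian normals (each
Gaussian's normal is the rotation axis of its smallest activated scale,
flipped toward the camera), and the accumulated alpha.

The backward pass is fully analytic, including the perspective Jacobian's
dependence on the mean, the quaternion normalization, and the normalization
of the composited depth and normal outputs. Gradients of the image-space
losses (including SSIM, via the adjoint of its separable Gaussian filter,
and the depth-normal consistency term, via the vector-Jacobian product of
the depth-to-normal map) are assembled in R and propagated through the
compositing in compiled code. The unit tests verify every parameter group
against central finite differences at `1e-3` relative tolerance; in
practice the agreement is `~1e-5`.

Two genuine non-smoothnesses of the model are worth knowing about: the
depth *sort* makes the render discontinuous in `z` exactly at depth ties
between overlapping Gaussians, and the `1/255` minimum-alpha cut introduces
negligible but nonzero kinks. Gradient checks therefore use configurations
with distinct depths, which is also the generic case in real optimization.

# Loss weights and optimizer

The combined loss uses `l_ssim = 0.2`, `l_d = 0.5`, `l_c = 0.05`,
`l_n: l_1 = 0.05, l_2 = 0.01`, `l_o = 0.01` -- the orders of magnitude
established by the upstream splatting literature, exposed in
`loss_weights()`. Depth-dependent terms are in millimetres (`L_d` is a mean
absolute error in mm), so `l_d = 0.5` makes geometric supervision the
dominant term early in training, which is the intended regime: photometric
optimization alone leaves floaters because constrained arthroscopic motion
under-determines geometry.

Optimization is Adam with per-group step sizes (positions `2e-4 x` scene
extent, scales `5e-3`, rotations `1e-3`, opacity logits `5e-2`, colors
`2.5e-3`), one keyframe per iteration in a deterministic round-robin.
`L_c`/`L_n` are evaluated on pixels with rendered alpha above 0.5, and
`L_d` additionally requires valid pseudo-depth.

## Opacity management

With the mean-aggregated `L_o` at `l_o = 0.01`, the per-Gaussian
binarization gradient is two orders of magnitude weaker than the
photometric noise, so the regularizer alone cannot lift a dense cloud of
overlapping Gaussians out of its translucent equilibrium: many Gaussians at
opacity 0.1-0.2 render the same image as few opaque ones, and every
downstream consumer -- the exported point cloud and the AR operators, all of
which gate on opacity 0.5 -- then sees almost nothing. Binarization is
therefore driven by a prune-and-refill cycle, both halves of which run
every 150 iterations by default:

* **pruning** removes Gaussians with activated opacity below 0.3. Each
  removal creates a coverage deficit that the photometric and depth losses
  repair by raising the survivors' opacities, so repeated pruning polarizes
  the cloud upward; `L_o` then keeps the survivors saturated. A
  `prune_max_frac` cap (off by default) is available to thin more gently,
  and a two-value `prune_threshold` ramps the cutoff linearly instead.
* **densification** (the minimal gradient-threshold clone/split) restores
  the spatial resolution that pruning costs: surviving -- hence opaque --
  Gaussians with a positional gradient are cloned with jitter, large ones
  are split with reduced scales; densification stops once the cloud exceeds
  a size cap (2500 by default). Pruning alone ends with a few hundred large
  opaque Gaussians, which renders well but quantizes the AR annotation
  masks; with refill the model settles near the cap with ~95% of Gaussians
  above 0.5 opacity.

This schedule -- not the opacity loss weight, which stays at the literature
default -- is what produces the near-binary, surface-aligned cloud the AR
tools assume.

# The synthetic scene generator

The generator emulates the *products* of the out-of-scope neural
components, not the components themselves, at knee-arthroscopy scale
(1 unit = 1 mm):

* **Surface**: a smooth random heightfield (5-20 Gaussian bumps, widths
  5-15 mm, amplitudes within 3 mm over a 50 mm domain) with one optional
  concave cavity (depth 6 mm, radius 8 mm) -- a low-relief articular
  surface with one distinctive indentation. Region labels (Voronoi cells of
  random seeds; the cavity has its own label) stand in for anatomical
  structures.
* **Texture and shading**: a low-contrast mottled albedo around a
  tissue-like base color, shaded as `albedo * (0.7 + 0.3 <n, -d>)` -- a
  headlight Lambertian term whose intensity changes with the camera pose,
  as an endoscope's coaxial illumination does. The 0.7 ambient share keeps
  the view-dependent component moderate, consistent with a flooded,
  close-range cavity; it is a generator constant, not a tuning knob.
* **Trajectory**: the camera tip sits at the end of a rigid scope pivoting
  about a fixed entry portal. `pivoting` sweeps the scope axis over a cone
  (tip on a sphere around the portal), `forward_backward` slides the tip
  along the axis (10-22 mm), `common` (default) combines both. Working
  distances come out at roughly 8-25 mm.
* **Disparity**: per frame, `raw = (depth - B_true) / A_true` with
  `(A_true, B_true)` drawn per frame, plus i.i.d. Gaussian noise (default
  1% of the raw range), then min-max normalized to `[0, 1]` over hit pixels
  -- exactly the scale/shift-free product of a relative-depth network. The
  realized post-normalization affine parameters are recorded so recovery
  can be scored against an exact truth.
* **Sparse prior**: 2000 surface points sampled through random hit pixels,
  observed in every keyframe where an occlusion test passes, with 0.5 px
  observation noise and 1%-of-depth 3D noise.

What the generator does *not* emulate: specularities, fluid and debris,
motion blur, rolling shutter, lens distortion, deformation, and the
spatially correlated failure modes of real depth networks (only an optional
low-frequency bias field is provided as a stress knob). Passing tests on
these scenes therefore validates the geometry and optimization machinery,
not robustness to real arthroscopic imagery.

# Numerical choices

* `fit_affine` keeps Nelder-Mead as the optimizer of record but initializes
  it at the closed-form OLS solution (`reltol 1e-10`, max 500 iterations),
  so its objective can never exceed the closed-form optimum beyond
  round-off. A negative fitted `A` is allowed with a warning (the disparity
  convention of an arbitrary network is not fixed); an optional single
  3-MAD residual-trimming pass is available for drifting tracks.
* Disparity at sub-pixel observations is sampled bilinearly. On a curved
  surface this introduces an `O(curvature x px^2)` inconsistency (~1e-4 mm
  at the default resolution) between interpolated disparity and the true
  point depth, which is the accuracy floor of the "noiseless" sequence
  tests; exact identities are asserted at pixel centers.
* Depth-to-normal uses central differences, one-sided at image borders;
  pixels adjacent to holes are invalid rather than differenced across the
  discontinuity.
* ICP is a similarity (7-DoF) alignment, since monocular reconstruction is
  scale-ambiguous. The closed-form similarity fit is the Umeyama solution;
  initialization matches centroids, RMS spreads and principal axes, trying
  all four proper axis-sign combinations plus identity (a single
  centroid/spread start stalls in local minima for large rotations). Each
  start gets a short coarse pass; starts are compared by the *symmetric*
  RMSE -- the directed source-to-target RMSE alone is gamed by a degenerate
  scale collapse onto a single target point -- and only the winner is
  refined to convergence. Nearest-neighbour lookups use a uniform-grid
  spatial hash, exact but much faster than brute force at the package's
  cloud sizes.
* SSIM is the standard 11x11 Gaussian-window formulation (sigma 1.5,
  `C1 = 0.01^2`, `C2 = 0.03^2`, peak 1) on the valid (fully-windowed)
  region; PSNR uses peak 1 and reports identical images as `Inf`, excluded
  from averages.
* The measurement study matches each picked endpoint to its nearest
  ground-truth surface point and compares the two Euclidean distances; the
  reference scene is sampled at 100k surface points.

# Problem sizes

The bundled study configuration -- 64x64 images, 100-frame trajectories
with every 5th frame as a keyframe, 2000 initial Gaussians, 1500 training
iterations -- reconstructs a scene in a few minutes on one CPU core. These
sizes were chosen so that the full pipeline, its ablation (training with
and without depth supervision), and the AR studies all run comfortably
inside a test suite while leaving the conclusions qualitative unchanged at
higher resolutions: every mechanism (scale recovery, depth supervision,
normal regularization, anchoring) is resolution-independent.

# Known limitations

* The renderer is a desk-scale CPU implementation; it is faithful but not
  real-time. Tile-based GPU rasterization is out of scope.
* Degree-0 color cannot represent view-dependent shading; the generator's
  moderate headlight term and any real specularity are absorbed as
  slightly blurred albedo, capping achievable PSNR.
* Keyframe selection is uniform subsampling, standing in for a SLAM's
  similarity-based selection.
* The affine disparity-to-depth model is applied to disparity as stated by
  the method (`D = A d + B`); physically depth is closer to affine in
  *inverse* disparity. An inverse-disparity mode exists behind
  `fit_affine`'s input transformation but is not the default, and the
  synthetic generator produces disparity that exactly satisfies the affine
  model, so this choice is untested against real networks.
* Dynamic or deformable scenes are not modeled.
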