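# arthrosplat

Dense, metrically consistent 3D reconstruction of arthroscopic (joint
endoscopy) scenes from the products of a monocular video front end — and the
augmented-reality measurement and annotation tools such a reconstruction
enables.

Arthroscopic video gives a surgeon a narrow, monocular view of low-texture
articular surfaces. A SLAM system can recover camera poses `T_i ∈ SE(3)` and
a *sparse* 3D point map from it, and a monocular depth network can produce
dense per-frame disparity maps `d` — but each disparity map is only defined
up to an unknown scale and shift. `arthrosplat` implements the stage in
between and everything downstream:

* **Per-keyframe scale recovery** — fit `D_pseudo = A·d + B` by minimizing
  `Σ (X_z − (A·x_d + B))²` over 2D–3D correspondences between the sparse
  map and the disparity map (Nelder–Mead started at the closed-form
  least-squares solution), giving temporally consistent metric pseudo-depth.
* **Depth-to-normal conversion** — camera-facing unit normal maps from
  finite-difference tangents of the backprojected point map.
* **Surface-aligned 3D Gaussian splatting** — an explicit Gaussian cloud
  optimized with a differentiable CPU renderer (analytic gradients) under
  the five-term loss
  `L = (1−λ_ssim)L1 + λ_ssim·L_D-SSIM + λ_d·L_d + λ_o·L_o + λ_c·L_c + λ_n·L_n`
  combining photometric error, pseudo-depth supervision
  (`L_d = ‖D̂ − D_pseudo‖₁`), opacity binarization
  (`L_o = exp(−(o−0.5)²/0.05)`), depth-normal consistency
  (`L_c = 1 − N̂·N(D̂)`), and a normal prior
  (`L_n = λ₁(1 − N̂·N_pseudo) + λ₂‖∇N̂‖₁`).
* **AR tools** — point picking and Euclidean measurement on the rendered
  scene; anchoring a 2D mask to the 3D Gaussians that generated it, so the
  highlight persists across viewpoints.
* **The full evaluation protocol** — similarity (7-DoF) ICP alignment,
  point-to-point RMSE, Hausdorff distance, PSNR, SSIM, mask mIoU, and a
  randomized 500-pair measurement-error study.
* **A seeded synthetic scene generator** — articular-like heightfields,
  portal-constrained camera trajectories, simulated sparse priors,
  min-max-normalized affine-distorted disparity, and region masks — so the
  entire pipeline is testable without external recordings or neural models.

## Worked example

Reconstruct a synthetic knee-like scene end to end and measure it:

```r
library(arthrosplat)

res <- run_pipeline(pipeline_config(), seed = 1, out_dir = "run1")
str(res$report)
```

On a single CPU core this takes five to ten minutes and prints:

```
List of 12
 $ rmse_mm                      : num 0.454
 $ hausdorff_mm                 : num 18
 $ icp_scale                    : num 1.07
 $ psnr_train_mean              : num 47.1
 $ ssim_train_mean              : num 0.997
 $ psnr_heldout_mean            : num 47.6
 $ ssim_heldout_mean            : num 0.997
 $ measure_median_error_mm      : num 0.0995
 $ measure_mean_error_mm        : num 0.111
 $ measure_median_gt_distance_mm: num 9.13
 $ annotation_miou              : num 0.766
 $ annotation_iou_sd            : num 0.113
```

`rmse_mm` is the point-to-point error of the exported Gaussian centers
against 50k samples of the ground-truth surface after similarity ICP —
half a millimetre at knee scale (the Hausdorff maximum is driven by a few
stray Gaussians). `psnr_heldout_mean`/`ssim_heldout_mean` score re-rendered
*held-out* camera poses against the ground-truth renderer.
`measure_median_error_mm` is the median absolute error of 500 AR distance
measurements between randomly picked point pairs, about 1% of the 9 mm
median pair distance. `annotation_miou` is the mean IoU between re-rendered
anchored annotations and the ground-truth region masks over the keyframes
where the region is most visible; it varies with how prominently the scene
seed exposes the cavity. The directory `run1/` holds the exported scene
(PNG/NPY/PLY/TUM/JSON), the trained model (`model.ply`, the de-facto splat
PLY layout readable by external viewers), per-iteration loss history,
the per-pair measurement study, and `report.json`.

The stages are equally usable on their own:

```r
sc     <- make_scene(scene_config(motion = "pivoting"), seed = 7)
kfs    <- scene_keyframes(sc, seed = 7)
prior  <- simulate_sparse_prior(sc, seed = 7)
rec    <- recover_sequence(prior, kfs$frames)
rec$params[[1]]
#> affine_depth_params (frame 1): A=6.54174 B=13.871, rms 0.1827 mm over n=1171
```

A command-line front end for shell use lives in `inst/cli/arsplat.R`
(`run`, `synth`, `train`, `render`, `measure`, `annotate`, `evaluate`).

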