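# End-to-end orchestration: synthetic generation (or external import) ->
# scale recovery -> normals -> Gaussian-splat training -> evaluation ->
# optional AR demo, with standard-format artifacts and a manifest.

#' Pipeline configuration
#'
#' @param scene A [scene_config()] (used when `stages$synth` is on).
#' @param weights [loss_weights()].
#' @param train [train_config()].
#' @param stages Named logical list: `synth`, `scale`, `train`, `evaluate`,
#'   `ar_demo`. A stage turned off reuses the artifacts already present in
#'   the output directory.
#' @param n_pairs Measurement-study pairs (evaluate/ar stage).
#' @param eval_samples Ground-truth surface samples for the cloud metrics.
#' @param export_threshold Opacity cutoff for the exported point cloud.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(), weights = loss_weights(),
                            train = train_config(),
                            stages = list(synth = TRUE, scale = TRUE,
                                          train = TRUE, evaluate = TRUE,
                                          ar_demo = TRUE),
                            n_pairs = 500, eval_samples = 50000,
                            export_threshold = 0.5) {
  structure(as.list(environment()), class = "pipeline_config")
}

# attach pseudo-depth and pseudo-normal maps to keyframes from a
# recover_sequence() result
attach_pseudo_maps <- function(frames, recovery) {
  for (j in seq_along(frames)) {
    pd <- recovery$pseudo_depth[[j]]
    if (is.null(pd)) next
    frames[[j]]$pseudo_depth <- pd
    frames[[j]]$normal <-
      depth_to_normal(pd, frames[[j]]$intrinsics)$normals
  }
  frames
}

#' Export a synthetic scene to standard formats
#'
#' Writes intrinsics JSON, the full TUM trajectory, per-keyframe PNG images,
#' ground-truth depth and simulated disparity as NPY, the sparse prior as PLY
#' plus a JSON track file (frame -> `[point_id, u, v]`), region masks as PNG,
#' the ground-truth mesh as PLY, and a manifest with the seeds and true
#' parameters.
#'
#' @param scene A [make_scene()] scene.
#' @param dir Output directory (created).
#' @param keyframes Output of [scene_keyframes()] (regenerated if `NULL`).
#' @param prior Output of [simulate_sparse_prior()] (regenerated if `NULL`).
#' @param seed Seed used for regeneration.
#' @return `dir`, invisibly.
#' @export
export_scene <- function(scene, dir, keyframes = NULL, prior = NULL,
                         seed = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(keyframes)) keyframes <- scene_keyframes(scene, seed = seed)
  if (is.null(prior)) prior <- simulate_sparse_prior(scene, seed = seed)
  write_intrinsics_json(scene$intrinsics, file.path(dir, "intrinsics.json"))
  write_tum_trajectory(scene$trajectory, file.path(dir, "trajectory.txt"),
                       timestamps = seq_along(scene$trajectory) - 1)
  for (fr in keyframes$frames) {
    tag <- sprintf("%04d", fr$index)
    write_png_image(fr$image, file.path(dir, paste0("frame_", tag, ".png")))
    write_npy(fr$gt_depth, file.path(dir, paste0("depth_", tag, ".npy")))
    write_npy(ifelse(is.na(fr$disparity), 0, fr$disparity),
              file.path(dir, paste0("disparity_", tag, ".npy")))
  }
  V <- prior$points; colnames(V) <- c("x", "y", "z")
  write_ply(file.path(dir, "prior.ply"), V)
  tr <- split(prior$observations[, c("point", "u", "v")],
              prior$observations$frame)
  tracks <- lapply(tr, function(g) unname(as.matrix(g)))
  jsonlite::write_json(list(keyframes = prior$keyframes, tracks = tracks),
                       file.path(dir, "tracks.json"), digits = NA)
  nlab <- nrow(scene$region_seeds) + as.integer(!is.null(scene$cavity))
  for (lab in seq_len(nlab)) {
    m <- suppressWarnings(simulate_mask(scene, lab, scene$keyframes[1]))
    write_png_image(m, file.path(dir, sprintf("mask_region%d_frame%04d.png",
                                              lab, scene$keyframes[1])))
  }
  mesh <- scene_mesh(scene)
  write_ply(file.path(dir, "gt_mesh.ply"), mesh$vertices, mesh$faces)
  jsonlite::write_json(
    list(seed = scene$seed, config = unclass(scene$config),
         true_affine = scene$true_affine,
         effective_affine = keyframes$effective_affine),
    file.path(dir, "scene_manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}

#' Import an externally produced dataset
#'
#' Reads the products of a real SLAM/monocular-depth front end: a directory
#' of keyframe images, a TUM trajectory, intrinsics JSON, optional disparity
#' NPY maps, and an optional sparse prior (PLY points + JSON tracks). Frame
#' indices are taken from the image file names (`frame_<index>.png`). The
#' schema is validated strictly; errors name the offending file.
#'
#' @param image_dir Directory with `frame_*.png` keyframe images.
#' @param trajectory_file TUM trajectory covering all frame indices
#'   (line `i` = frame index `i - 1`... line order = frame order, 0-based
#'   timestamps used as frame indices).
#' @param intrinsics_file JSON intrinsics.
#' @param disparity_dir Optional directory with matching `disparity_*.npy`.
#' @param prior_ply,tracks_json Optional sparse prior files.
#' @return A list with `frames` (list of [video_frame()]) and `prior`
#'   (a `sparse_prior` or `NULL`).
#' @export
import_external <- function(image_dir, trajectory_file, intrinsics_file,
                            disparity_dir = NULL, prior_ply = NULL,
                            tracks_json = NULL) {
  K <- read_intrinsics_json(intrinsics_file)
  traj <- read_tum_trajectory(trajectory_file)
  imgs <- sort(list.files(image_dir, pattern = "^frame_\\d+\\.png$",
                          full.names = TRUE))
  if (length(imgs) == 0) stop("import_external: no frame_*.png in ", image_dir)
  idx <- as.integer(sub(".*frame_(\\d+)\\.png$", "\\1", imgs))
  frame_of_ts <- match(idx - 1, traj$timestamps)
  if (anyNA(frame_of_ts))
    stop("import_external: trajectory is missing frame ",
         idx[which(is.na(frame_of_ts))[1]])
  frames <- vector("list", length(imgs))
  for (j in seq_along(imgs)) {
    img <- read_png_image(imgs[j])
    if (is.matrix(img)) {
      img <- array(rep(img, 3), c(dim(img), 3))
    }
    if (!all(dim(img)[1:2] == c(K$height, K$width)))
      stop("import_external: image size mismatch in ", imgs[j])
    disp <- NULL
    if (!is.null(disparity_dir)) {
      df <- file.path(disparity_dir, sprintf("disparity_%04d.npy", idx[j]))
      if (!file.exists(df))
        stop("import_external: missing disparity file ", df)
      disp <- read_npy(df)
      if (!all(dim(disp) == c(K$height, K$width)))
        stop("import_external: disparity size mismatch in ", df)
      disp[disp == 0] <- NA_real_
    }
    frames[[j]] <- video_frame(idx[j], img, traj$poses[[frame_of_ts[j]]], K,
                               disparity = disp)
  }
  prior <- NULL
  if (!is.null(prior_ply)) {
    if (is.null(tracks_json))
      stop("import_external: prior_ply given without tracks_json")
    P <- read_ply(prior_ply)$vertices[, c("x", "y", "z"), drop = FALSE]
    tj <- jsonlite::read_json(tracks_json, simplifyVector = TRUE)
    obs <- do.call(rbind, lapply(names(tj$tracks), function(f) {
      m <- matrix(unlist(tj$tracks[[f]]), ncol = 3,
                  byrow = !is.matrix(tj$tracks[[f]]))
      if (is.matrix(tj$tracks[[f]])) m <- tj$tracks[[f]]
      data.frame(point = as.integer(m[, 1]), frame = as.integer(f),
                 u = m[, 2], v = m[, 3])
    }))
    if (max(obs$point) > nrow(P))
      stop("import_external: track point id exceeds prior size in ",
           tracks_json)
    prior <- structure(list(points = P, true_points = NULL, colors = NULL,
                            observations = obs,
                            keyframes = as.integer(tj$keyframes)),
                       class = "sparse_prior")
  }
  list(frames = frames, prior = prior)
}

#' Run the full reconstruction-and-AR pipeline
#'
#' Executes the enabled stages on a synthetic scene (deterministic in
#' `seed`): scene synthesis, per-keyframe scale recovery and pseudo-depth /
#' pseudo-normal generation, Gaussian-splat training, the evaluation
#' protocol (ICP-aligned cloud RMSE/Hausdorff, keyframe and held-out
#' PSNR/SSIM), and the AR demo (measurement-error study, mask annotation
#' with mIoU). Artifacts land in `out_dir`: `scene/`, `pseudo_depth/`,
#' `normals/`, `model.ply`, `history.csv`, `report.json`, `study.csv`,
#' `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param seed Global integer seed; every stochastic stage derives its own
#'   seed from it.
#' @param out_dir Output directory.
#' @return A list with `report` (the metric list), `cloud`, `scene`, and
#'   `paths`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 0,
                         out_dir = tempfile("arsplat_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  timing <- list(); t_all <- Sys.time()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))
  stage_fail <- function(stage, e)
    stop(sprintf("run_pipeline: stage '%s' failed: %s (partial artifacts in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  # --- scene ------------------------------------------------------------
  t0 <- tic()
  scene <- tryCatch(make_scene(config$scene, seed = seed),
                    error = function(e) stage_fail("synth", e))
  kfs <- tryCatch(scene_keyframes(scene, seed = seed),
                  error = function(e) stage_fail("synth", e))
  prior <- tryCatch(simulate_sparse_prior(scene, seed = seed),
                    error = function(e) stage_fail("synth", e))
  if (isTRUE(st$synth))
    export_scene(scene, file.path(out_dir, "scene"), kfs, prior, seed = seed)
  timing$synth <- toc(t0)
  # --- scale recovery + normals ----------------------------------------
  t0 <- tic()
  rec <- tryCatch(recover_sequence(prior, kfs$frames),
                  error = function(e) stage_fail("scale", e))
  frames <- attach_pseudo_maps(kfs$frames, rec)
  if (isTRUE(st$scale)) {
    pdir <- file.path(out_dir, "pseudo_depth")
    ndir <- file.path(out_dir, "normals")
    dir.create(pdir, showWarnings = FALSE); dir.create(ndir,
                                                       showWarnings = FALSE)
    aff <- lapply(rec$params, function(p)
      list(frame = p$frame_index, A = p$A, B = p$B,
           residual_rms = p$residual_rms, n = p$n_correspondences))
    jsonlite::write_json(aff, file.path(out_dir, "affine_params.json"),
                         auto_unbox = TRUE, digits = NA)
    for (fr in frames) {
      if (is.null(fr$pseudo_depth)) next
      tag <- sprintf("%04d", fr$index)
      write_npy(fr$pseudo_depth, file.path(pdir, paste0("pseudo_", tag,
                                                        ".npy")))
      write_npy(fr$normal, file.path(ndir, paste0("normal_", tag, ".npy")))
    }
  }
  timing$scale <- toc(t0)
  # --- training ---------------------------------------------------------
  model_path <- file.path(out_dir, "model.ply")
  t0 <- tic()
  if (isTRUE(st$train)) {
    cloud0 <- init_from_points(prior$points, prior$colors)
    tc <- config$train; tc$seed <- derive_seed(seed, "train")
    fit <- tryCatch(train_gaussians(cloud0, frames, config$weights, tc),
                    error = function(e) stage_fail("train", e))
    cloud <- fit$cloud
    write_gaussian_ply(cloud, model_path)
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  } else {
    if (!file.exists(model_path))
      stop("run_pipeline: train stage off and no cached model.ply in ",
           out_dir)
    cloud <- read_gaussian_ply(model_path)
  }
  timing$train <- toc(t0)
  # --- evaluation -------------------------------------------------------
  report <- list()
  t0 <- tic()
  if (isTRUE(st$evaluate)) {
    mesh <- scene_mesh(scene)
    gtpts <- sample_mesh(mesh, config$eval_samples,
                         seed = derive_seed(seed, "eval"))
    pts <- export_point_cloud(cloud, config$export_threshold)
    al <- tryCatch(align_icp(pts, gtpts),
                   error = function(e) stage_fail("evaluate", e))
    report$rmse_mm <- rmse_point_to_point(al$aligned, gtpts)
    report$hausdorff_mm <- hausdorff_distance(al$aligned, gtpts)
    report$icp_scale <- al$scale
    ps <- ss <- numeric(0)
    for (fr in frames) {
      r <- render_gaussians(cloud, fr$pose, fr$intrinsics)
      img <- pmin(pmax(r$image, 0), 1)
      ps <- c(ps, psnr(img, fr$image)); ss <- c(ss, ssim(img, fr$image))
    }
    report$psnr_train_mean <- mean(ps[is.finite(ps)])
    report$ssim_train_mean <- mean(ss)
    held <- setdiff(round(seq(3, scene$config$n_frames - 2, length.out = 5)),
                    scene$keyframes)
    ph <- sh <- numeric(0)
    for (i in held) {
      gt <- render_ground_truth(scene, i)
      r <- render_gaussians(cloud, scene$trajectory[[i]], scene$intrinsics)
      img <- pmin(pmax(r$image, 0), 1)
      ph <- c(ph, psnr(img, gt$image)); sh <- c(sh, ssim(img, gt$image))
    }
    report$psnr_heldout_mean <- mean(ph[is.finite(ph)])
    report$ssim_heldout_mean <- mean(sh)
  }
  timing$evaluate <- toc(t0)
  # --- AR demo ----------------------------------------------------------
  t0 <- tic()
  if (isTRUE(st$ar_demo)) {
    study <- tryCatch(
      measurement_error_study(scene, cloud, n_pairs = config$n_pairs,
                              seed = derive_seed(seed, "study")),
      error = function(e) stage_fail("ar_demo", e))
    utils::write.csv(study$pairs, file.path(out_dir, "study.csv"),
                     row.names = FALSE)
    report$measure_median_error_mm <- study$summary$median
    report$measure_mean_error_mm <- study$summary$mean
    report$measure_median_gt_distance_mm <- study$summary$median_gt_distance
    # annotation demo on the cavity (or region 1), anchored from the keyframe
    # where the region is most visible -- as an operator would choose
    lab <- if (!is.null(scene$cavity)) nrow(scene$region_seeds) + 1L else 1L
    kmasks <- lapply(scene$keyframes, function(i)
      suppressWarnings(simulate_mask(scene, lab, i)))
    f1 <- scene$keyframes[which.max(vapply(kmasks, sum, 0))]
    msk <- kmasks[[which.max(vapply(kmasks, sum, 0))]]
    anc <- anchor_annotation(cloud, scene$trajectory[[f1]], scene$intrinsics,
                             msk)
    # report stability over the keyframes where the region is most visible
    vis <- order(vapply(kmasks, sum, 0), decreasing = TRUE)
    vis <- vis[seq_len(min(10, length(vis)))]
    ious <- vapply(vis, function(j) {
      ra <- render_annotation(cloud, anc,
                              scene$trajectory[[scene$keyframes[j]]],
                              scene$intrinsics)
      miou(ra$mask, kmasks[[j]])
    }, 0)
    report$annotation_miou <- mean(ious)
    report$annotation_iou_sd <- stats::sd(ious)
    ra <- render_annotation(cloud, anc, scene$trajectory[[f1]],
                            scene$intrinsics)
    write_png_image(ra$image, file.path(out_dir, "annotation_demo.png"))
    jsonlite::write_json(list(indices = anc$gaussian_indices,
                              highlight = anc$highlight_color),
                         file.path(out_dir, "anchor.json"), digits = NA)
  }
  timing$ar_demo <- toc(t0)
  if (length(report) > 0)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("arthrosplat")),
                   seed = seed, timing = timing,
                   stages = st, metrics = report,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(report = report, cloud = cloud, scene = scene,
                 paths = list(out_dir = out_dir, model = model_path)))
}
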