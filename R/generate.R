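#' Benchmark generation configuration
#'
#' Default values reproduce the study conditions of the benchmark: 3500-point
#' source clouds, a 15% visible crop among points facing the camera within
#' 80 degrees, lobe displacements up to +/-25 mm on x and z, rigid
#' perturbations up to 45 degrees and +/-50 mm, and per-coordinate Gaussian
#' noise with standard deviation 0.01 in normalized units.
#'
#' @param n_source_points points sampled on the source mesh surface.
#' @param crop_ratio fraction of source points retained in the partial
#'   target (the benchmark uses 0.05, 0.10, 0.15 or 0.25).
#' @param visibility_angle_max maximum angle (degrees) between a point's
#'   outward normal and the direction to the camera for the point to count
#'   as visible.
#' @param deform_max maximum absolute lobe displacement (mm) along x and z.
#' @param rot_max maximum rigid-perturbation rotation angle (degrees).
#' @param trans_max maximum absolute rigid-perturbation translation
#'   component (mm).
#' @param noise_sigma per-coordinate Gaussian noise standard deviation,
#'   in normalized units.
#' @param n_landmarks number of TRE landmark pairs taken from cropped-out
#'   regions.
#' @param master_seed integer master seed for dataset-level seeding.
#' @param handle_margin fraction of the half-extent excluded around the
#'   lobe split plane when picking handles/anchors.
#' @param arap_iters local-global deformation iterations.
#' @param normals_k neighbourhood size for normal estimation.
#' @param camera_polar_range,camera_azimuth_range,camera_radius_factor
#'   virtual-camera placement: polar/azimuth ranges (degrees) and radius as
#'   a multiple of the bounding-sphere radius, spanning typical
#'   intraoperative viewpoints.
#' @return an object of class `generation_config`.
#' @export
generation_config <- function(n_source_points = 3500L,
                              crop_ratio = 0.15,
                              visibility_angle_max = 80,
                              deform_max = 25,
                              rot_max = 45,
                              trans_max = 50,
                              noise_sigma = 0.01,
                              n_landmarks = 20L,
                              master_seed = 0L,
                              handle_margin = 0.3,
                              arap_iters = 10L,
                              normals_k = 20L,
                              camera_polar_range = c(15, 75),
                              camera_azimuth_range = c(0, 360),
                              camera_radius_factor = 2.5) {
  stopifnot(crop_ratio > 0, crop_ratio < 1,
            visibility_angle_max > 0, visibility_angle_max < 90,
            deform_max >= 0, rot_max >= 0, trans_max >= 0, noise_sigma >= 0,
            n_source_points >= 4, n_landmarks >= 1)
  structure(list(n_source_points = as.integer(n_source_points),
                 crop_ratio = crop_ratio,
                 visibility_angle_max = visibility_angle_max,
                 deform_max = deform_max, rot_max = rot_max,
                 trans_max = trans_max, noise_sigma = noise_sigma,
                 n_landmarks = as.integer(n_landmarks),
                 master_seed = as.integer(master_seed),
                 handle_margin = handle_margin,
                 arap_iters = as.integer(arap_iters),
                 normals_k = as.integer(normals_k),
                 camera_polar_range = camera_polar_range,
                 camera_azimuth_range = camera_azimuth_range,
                 camera_radius_factor = camera_radius_factor),
            class = "generation_config")
}

#' Draw a random rigid perturbation
#'
#' Rotation axis uniform on the unit sphere, rotation angle uniform on
#' `[0, rot_max]` degrees, translation components independent uniform on
#' `[-trans_max, trans_max]` (mm). The rotation is about the origin; the
#' pair generator recentres it on the cloud centroid so the translation
#' bounds stay meaningful.
#'
#' @param seed integer seed; the same seed returns the same transform.
#' @param rot_max maximum rotation angle, degrees.
#' @param trans_max maximum absolute translation component, mm.
#' @return a `rigid_transform` with translation in mm.
#' @export
sample_rigid_perturbation <- function(seed, rot_max = 45, trans_max = 50) {
  draw <- withr::with_seed(seed, {
    ax <- rnorm(3)
    list(axis = ax / sqrt(sum(ax^2)),
         angle = runif(1, 0, rot_max),
         t = runif(3, -trans_max, trans_max))
  })
  rigid_transform(axis_angle_matrix(draw$axis, draw$angle), draw$t)
}

#' Rotation matrix from axis and angle (degrees)
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
axis_angle_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Draw a random lobe displacement
#'
#' Independent uniform components on `[-deform_max, deform_max]` along x and
#' z (the in-plane directions of the lobe shift); the y component is zero.
#'
#' @param seed integer seed.
#' @param deform_max maximum absolute displacement (mm) along x and z.
#' @return length-3 displacement vector in mm.
#' @export
sample_lobe_displacement <- function(seed, deform_max = 25) {
  d <- withr::with_seed(seed, runif(2, -deform_max, deform_max))
  c(d[1], 0, d[2])
}

#' Sample a virtual endoscope pose
#'
#' Camera position drawn in spherical coordinates about the mesh centre at
#' `radius_factor` times the bounding-sphere radius, with polar and azimuth
#' angles uniform in the configured ranges; the look direction points at the
#' centre.
#'
#' @param mesh_bounds 2 x 3 matrix of per-axis (min, max), or an object with
#'   points/vertices from which bounds are taken.
#' @param seed integer seed.
#' @param polar_range,azimuth_range angle ranges in degrees.
#' @param radius_factor camera distance as a multiple of the bounding-sphere
#'   radius.
#' @return an object of class `camera_spec` with `position` (mm) and unit
#'   `look_direction`.
#' @export
sample_camera <- function(mesh_bounds, seed, polar_range = c(15, 75),
                          azimuth_range = c(0, 360), radius_factor = 2.5) {
  b <- coerce_bounds(mesh_bounds)
  ctr <- colMeans(b)
  radius <- sqrt(sum((b[2, ] - b[1, ])^2)) / 2
  ang <- withr::with_seed(seed, {
    list(polar = runif(1, polar_range[1], polar_range[2]),
         azimuth = runif(1, azimuth_range[1], azimuth_range[2]))
  })
  th <- ang$polar * pi / 180; ph <- ang$azimuth * pi / 180
  pos <- ctr + radius_factor * radius *
    c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  look <- (ctr - pos) / sqrt(sum((ctr - pos)^2))
  structure(list(position = pos, look_direction = look,
                 polar = ang$polar, azimuth = ang$azimuth),
            class = "camera_spec")
}

coerce_bounds <- function(x) {
  if (is.matrix(x) && nrow(x) == 2 && ncol(x) == 3) return(x)
  pts <- if (inherits(x, "triangle_mesh")) x$vertices
         else if (inherits(x, "point_cloud")) x$points
         else as_coord_matrix(x, "bounds input")
  apply(pts, 2, range)
}

#' Crop a cloud to the surface patch visible from a camera
#'
#' Candidate points are those whose outward normal makes an angle smaller
#' than `angle_max` with the direction to the camera. Exactly
#' `round(crop_ratio * N)` points are retained as one contiguous view patch:
#' the candidate nearest the camera seeds the patch, which then grows by
#' Euclidean nearest-neighbour accretion among candidates, mimicking a
#' single endoscopic view rather than a dispersed thinning.
#'
#' @param cloud a `point_cloud` with normals.
#' @param camera a `camera_spec`.
#' @param crop_ratio fraction of the full cloud to retain (0 < ratio < 1).
#' @param angle_max visibility angle threshold, degrees.
#' @return integer vector of retained point indices.
#' @export
visibility_crop <- function(cloud, camera, crop_ratio, angle_max = 80) {
  if (is.null(cloud$normals)) stop("visibility_crop requires normals")
  if (crop_ratio <= 0 || crop_ratio >= 1) stop("crop_ratio must be in (0, 1)")
  pts <- cloud$points
  to_cam <- sweep(-pts, 2, camera$position, "+")
  to_cam <- to_cam / sqrt(rowSums(to_cam^2))
  cosang <- rowSums(cloud$normals * to_cam)
  cand <- which(cosang > cos(angle_max * pi / 180))
  n_keep <- round(crop_ratio * nrow(pts))
  if (length(cand) < n_keep) {
    stop(structure(class = c("liverbench_visibility_error", "error", "condition"),
                   list(message = sprintf(
                     "only %d of the required %d points pass the visibility test",
                     length(cand), n_keep), call = sys.call(-1))))
  }
  cpts <- pts[cand, , drop = FALSE]
  dcam <- rowSums(sweep(cpts, 2, camera$position)^2)
  sel <- integer(n_keep)
  sel[1] <- which.min(dcam)
  mind <- rowSums(sweep(cpts, 2, cpts[sel[1], ])^2)
  mind[sel[1]] <- Inf
  if (n_keep > 1) {
    for (i in 2:n_keep) {
      m <- min(mind)
      ties <- which(mind <= m + 1e-12 * max(m, 1))
      j <- ties[which.min(dcam[ties])]  # ties accrete toward the camera
      sel[i] <- j
      d2 <- rowSums(sweep(cpts, 2, cpts[j, ])^2)
      mind <- pmin(mind, d2)
      mind[sel[seq_len(i)]] <- Inf
    }
  }
  sort(cand[sel])
}

#' Add element-wise Gaussian noise to a cloud
#'
#' Independent zero-mean Gaussian perturbation of every coordinate,
#' emulating stereo-reconstruction noise; `sigma` is in the cloud's units
#' (the benchmark applies 0.01 in the normalized frame).
#'
#' @param cloud a `point_cloud`.
#' @param sigma noise standard deviation.
#' @param seed integer seed.
#' @return the noisy `point_cloud` (normals carried over unchanged).
#' @export
add_gaussian_noise <- function(cloud, sigma = 0.01, seed = 0L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(cloud)
  n <- nrow(cloud$points)
  eps <- withr::with_seed(seed, matrix(rnorm(n * 3, 0, sigma), n, 3))
  point_cloud(cloud$points + eps, cloud$normals, cloud$frame)
}

#' Select TRE landmarks from the cropped-out surface
#'
#' Landmarks are chosen by farthest point sampling over the points NOT
#' visible in the partial target, so they can never leak into the
#' registration inputs; each landmark pairs a rest-surface position with the
#' same-index position on the deformed surface.
#'
#' @param source_points N x 3 rest-surface sample positions.
#' @param deformed_points N x 3 positions of the same samples after
#'   deformation.
#' @param visible_indices indices retained in the partial target.
#' @param n number of landmarks.
#' @param start 1-based position (within the cropped-out subset) of the
#'   first landmark; defaults to the first cropped-out point.
#' @return list with `indices` (into the source sample), `source` and
#'   `target` (n x 3 matrices of paired positions).
#' @export
select_landmarks <- function(source_points, deformed_points, visible_indices,
                             n = 20L, start = 1L) {
  cropped <- setdiff(seq_len(nrow(source_points)), visible_indices)
  if (length(cropped) < n) {
    stop("cropped-out region has only ", length(cropped), " points; need ", n)
  }
  sel <- farthest_point_sampling(source_points[cropped, , drop = FALSE], n, start)
  idx <- cropped[sel]
  list(indices = idx,
       source = source_points[idx, , drop = FALSE],
       target = deformed_points[idx, , drop = FALSE])
}

#' Generate one complete-to-partial benchmark pair
#'
#' Runs the full synthesis pipeline on a source mesh: (1) area-weighted
#' surface sampling; (2) seeded lobe choice and displacement applied through
#' as-rigid-as-possible deformation, with the same barycentric coordinates
#' carried onto the deformed mesh so source/deformed correspondence is
#' index-exact; (3) normal estimation, virtual-camera draw and visibility
#' crop to `crop_ratio`; (4) overlap labels and the target-to-source
#' correspondence map; (5) landmark selection from the cropped-out region;
#' (6) isotropic normalization of both clouds with the source cloud's map;
#' (7) seeded rigid perturbation of the target (and target landmarks) in
#' normalized units, with mm bounds converted through the map; (8) additive
#' Gaussian noise on the target. A failed visibility crop retries with a
#' re-derived camera seed up to 10 times.
#'
#' @param mesh the source `triangle_mesh` (metric mm).
#' @param config a `generation_config`.
#' @param seed the per-pair seed controlling every stochastic stage.
#' @return an object of class `pair_record`.
#' @export
generate_pair <- function(mesh, config = generation_config(), seed = 0L) {
  src <- sample_surface_points(mesh, config$n_source_points,
                               seed = derive_seed(seed, "sample"),
                               with_barycentric = TRUE)
  lobe <- if (withr::with_seed(derive_seed(seed, "lobe"), runif(1)) < 0.5) "left" else "right"
  disp <- sample_lobe_displacement(derive_seed(seed, "deform"), config$deform_max)
  if (config$deform_max > 0) {
    sel <- select_lobe_handles(mesh, lobe, config$handle_margin)
    dmesh <- arap_deform(mesh, sel$handles, sel$anchors, disp, config$arap_iters)
  } else {
    dmesh <- mesh
  }
  dpts <- barycentric_points(dmesh, attr(src, "face"), attr(src, "bary"))
  dcloud <- estimate_normals(point_cloud(dpts, frame = "metric_mm"), config$normals_k)

  visible <- NULL
  cam <- NULL
  for (attempt in 0:9) {
    cam <- sample_camera(dcloud$points, derive_seed(seed, paste0("camera", attempt)),
                         config$camera_polar_range, config$camera_azimuth_range,
                         config$camera_radius_factor)
    visible <- tryCatch(
      visibility_crop(dcloud, cam, config$crop_ratio, config$visibility_angle_max),
      liverbench_visibility_error = function(e) NULL)
    if (!is.null(visible)) break
  }
  if (is.null(visible)) stop("visibility crop failed after 10 camera draws (seed ", seed, ")")

  overlap <- integer(config$n_source_points)
  overlap[visible] <- 1L
  correspondence <- visible  # target row i corresponds to source index visible[i]

  lm <- select_landmarks(src$points, dpts, visible, config$n_landmarks)

  nz <- normalize_isotropic(point_cloud(src$points, frame = "metric_mm"))
  map <- nz$map
  source_n <- nz$cloud
  target_n <- point_cloud(map_to_normalized(dpts[visible, , drop = FALSE], map),
                          dcloud$normals[visible, , drop = FALSE], "normalized")
  lm_src_n <- map_to_normalized(lm$source, map)
  lm_tgt_n <- map_to_normalized(lm$target, map)

  pert <- sample_rigid_perturbation(derive_seed(seed, "rigid"),
                                    config$rot_max, config$trans_max)
  t_norm <- pert$translation / map$scale
  ctr <- colMeans(target_n$points)
  gt <- rigid_transform(pert$rotation,
                        as.numeric(ctr - pert$rotation %*% ctr) + t_norm)
  target_n <- apply_rigid(target_n, gt)
  lm_tgt_n <- apply_rigid(lm_tgt_n, gt)
  target_n <- add_gaussian_noise(target_n, config$noise_sigma,
                                 derive_seed(seed, "noise"))

  structure(list(
    source = source_n,
    target = target_n,
    gt_transform = gt,
    correspondence = correspondence,
    overlap_labels = overlap,
    landmarks_source = lm_src_n,
    landmarks_target = lm_tgt_n,
    landmark_indices = lm$indices,
    norm_map = map,
    seed = as.integer(seed),
    provenance = list(lobe = lobe, displacement_mm = disp, camera = cam,
                      crop_ratio = config$crop_ratio)
  ), class = "pair_record")
}

#' @exportS3Method base::print
print.pair_record <- function(x, ...) {
  cat(sprintf(paste0("<pair_record: source %d pts, target %d pts, ",
                     "crop %.0f%%, seed %d>\n"),
              n_points(x$source), n_points(x$target),
              100 * x$provenance$crop_ratio, x$seed))
  invisible(x)
}

#' Enumerate a dataset manifest without generating geometry
#'
#' Per-pair seeds are a stable hash of (master seed, source id, target
#' index), so any pair can be regenerated independently and all seeds are
#' distinct with overwhelming probability.
#'
#' @param source_ids character or integer identifiers of the source meshes.
#' @param targets_per_source partial targets generated per source.
#' @param config a `generation_config` (supplies the master seed).
#' @param split name of the split the manifest describes.
#' @return a tibble with columns `split`, `source_id`, `target_index`,
#'   `seed` and `path`.
#' @export
dataset_manifest <- function(source_ids, targets_per_source,
                             config = generation_config(), split = "train") {
  grid <- tidyr::expand_grid(source_id = as.character(source_ids),
                             target_index = seq_len(targets_per_source))
  seeds <- purrr::map2_int(grid$source_id, grid$target_index, function(s, t) {
    derive_seed(config$master_seed, paste0("pair/", s, "/", t))
  })
  tibble::tibble(split = split,
                 source_id = grid$source_id,
                 target_index = grid$target_index,
                 seed = seeds,
                 path = sprintf("%s_%s_%04d.json.gz", split, grid$source_id,
                                grid$target_index))
}

#' Generate a full dataset of benchmark pairs
#'
#' @param meshes named list of source `triangle_mesh` objects.
#' @param targets_per_source partial targets per source mesh.
#' @param config a `generation_config`.
#' @param out_dir if non-NULL, every pair is written there as a pair archive
#'   and the manifest as `manifest.json`.
#' @param split manifest split name.
#' @return the manifest tibble; when `out_dir` is given, pairs are written
#'   as a side effect and failures recorded in an `error` column.
#' @export
generate_dataset <- function(meshes, targets_per_source,
                             config = generation_config(), out_dir = NULL,
                             split = "test") {
  if (!length(meshes)) stop("at least one source mesh is required")
  if (is.null(names(meshes))) names(meshes) <- sprintf("mesh%02d", seq_along(meshes))
  man <- dataset_manifest(names(meshes), targets_per_source, config, split)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    man$error <- NA_character_
    for (i in seq_len(nrow(man))) {
      res <- tryCatch({
        pair <- generate_pair(meshes[[man$source_id[i]]], config, man$seed[i])
        write_pair_archive(pair, file.path(out_dir, man$path[i]))
        NA_character_
      }, error = function(e) conditionMessage(e))
      man$error[i] <- res
    }
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  man
}

#' Read / write a pair archive
#'
#' One gzip-compressed JSON container per pair holding the named arrays
#' (source, target, normals, ground-truth 4 x 4 matrix, correspondence,
#' overlap labels, landmarks, normalization map) plus provenance.
#'
#' @param pair a `pair_record`.
#' @param path output path (conventionally `.json.gz`).
#' @return `path` invisibly; `read_pair_archive` returns the `pair_record`.
#' @export
write_pair_archive <- function(pair, path) {
  obj <- list(
    source = pair$source$points,
    target = pair$target$points,
    target_normals = pair$target$normals,
    gt_matrix = as_homogeneous(pair$gt_transform),
    correspondence = pair$correspondence,
    overlap_labels = pair$overlap_labels,
    landmarks_source = pair$landmarks_source,
    landmarks_target = pair$landmarks_target,
    landmark_indices = pair$landmark_indices,
    norm_map = list(scale = pair$norm_map$scale, offset = pair$norm_map$offset),
    seed = pair$seed,
    provenance = list(lobe = pair$provenance$lobe,
                      displacement_mm = pair$provenance$displacement_mm,
                      camera_position = pair$provenance$camera$position,
                      camera_look = pair$provenance$camera$look_direction,
                      crop_ratio = pair$provenance$crop_ratio)
  )
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), con)
  invisible(path)
}

#' @rdname write_pair_archive
#' @export
read_pair_archive <- function(path) {
  obj <- jsonlite::fromJSON(readLines(gzfile(path)), simplifyVector = TRUE)
  map <- normalization_map(obj$norm_map$scale, obj$norm_map$offset)
  structure(list(
    source = point_cloud(obj$source, frame = "normalized"),
    target = point_cloud(obj$target, obj$target_normals, "normalized"),
    gt_transform = from_homogeneous(obj$gt_matrix),
    correspondence = as.integer(obj$correspondence),
    overlap_labels = as.integer(obj$overlap_labels),
    landmarks_source = as_coord_matrix(obj$landmarks_source, "landmarks"),
    landmarks_target = as_coord_matrix(obj$landmarks_target, "landmarks"),
    landmark_indices = as.integer(obj$landmark_indices),
    norm_map = map,
    seed = as.integer(obj$seed),
    provenance = list(lobe = obj$provenance$lobe,
                      displacement_mm = obj$provenance$displacement_mm,
                      camera = structure(list(position = obj$provenance$camera_position,
                                              look_direction = obj$provenance$camera_look),
                                         class = "camera_spec"),
                      crop_ratio = obj$provenance$crop_ratio)
  ), class = "pair_record")
}
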