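test_that("rigid perturbation sampler respects its bounds and is seeded", {
  draws <- lapply(0:499, function(s) sample_rigid_perturbation(s))
  angles <- vapply(draws, function(d) rotation_angle(d$rotation), 0)
  trans <- t(vapply(draws, function(d) d$translation, numeric(3)))
  expect_lte(max(angles), 45)
  expect_lte(max(abs(trans)), 50)
  expect_identical(sample_rigid_perturbation(7), sample_rigid_perturbation(7))
  expect_equal(sample_rigid_perturbation(3, rot_max = 0)$rotation, diag(3))

  # angle distribution uniform on [0, rot_max]
  many <- vapply(0:4999, function(s) {
    rotation_angle(sample_rigid_perturbation(s)$rotation)
  }, 0)
  ks <- suppressWarnings(stats::ks.test(many / 45, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("lobe displacement sampler stays within the x/z deformation range", {
  d <- t(vapply(0:999, function(s) sample_lobe_displacement(s), numeric(3)))
  expect_true(all(d[, 2] == 0))
  expect_lte(max(abs(d[, c(1, 3)])), 25)
  expect_identical(sample_lobe_displacement(5), sample_lobe_displacement(5))
})

test_that("camera sampler covers the configured angular ranges", {
  b <- rbind(c(-100, -50, -40), c(100, 50, 40))
  cams <- lapply(0:199, function(s) sample_camera(b, s))
  expect_true(all(vapply(cams, function(cm) {
    abs(sqrt(sum(cm$look_direction^2)) - 1) < 1e-9
  }, TRUE)))
  polars <- vapply(cams, function(cm) cm$polar, 0)
  expect_true(all(polars >= 15 & polars <= 75))
  fixed <- sample_camera(b, 3, polar_range = c(40, 40))
  expect_equal(fixed$polar, 40)
  # camera sits outside the organ bounding box
  pos <- t(vapply(cams, function(cm) cm$position, numeric(3)))
  outside <- pos[, 1] < b[1, 1] | pos[, 1] > b[2, 1] |
             pos[, 2] < b[1, 2] | pos[, 2] > b[2, 2] |
             pos[, 3] < b[1, 3] | pos[, 3] > b[2, 3]
  expect_true(all(outside))
})

test_that("visibility crop retains an exact-count, angle-valid view patch", {
  # plane with +z normals, camera straight above
  set.seed(13)
  g <- expand.grid(x = seq(0, 1, length.out = 20), y = seq(0, 1, length.out = 20))
  plane <- point_cloud(cbind(g$x, g$y, 0), cbind(0, 0, rep(1, nrow(g))))
  cam <- structure(list(position = c(0.5, 0.5, 5),
                        look_direction = c(0, 0, -1)), class = "camera_spec")
  idx <- visibility_crop(plane, cam, crop_ratio = 0.15)
  expect_length(idx, round(0.15 * 400))
  # the accreted patch closely matches the ideal disc of nearest points
  # around the camera axis (greedy accretion can differ at the rim)
  d_all <- sqrt(rowSums(sweep(plane$points, 2, cam$position)^2))
  disc <- order(d_all)[seq_along(idx)]
  expect_gte(length(intersect(idx, disc)) / length(idx), 0.9)

  flipped <- point_cloud(plane$points, -plane$normals)
  expect_error(visibility_crop(flipped, cam, 0.15), "visibility",
               class = "liverbench_visibility_error")

  cl <- default_pair()
  expect_equal(sum(cl$overlap_labels), 525)
})

test_that("gaussian noise stage matches its nominal standard deviation", {
  cl <- point_cloud(matrix(0, 1000, 3), frame = "normalized")
  expect_identical(add_gaussian_noise(cl, 0, 1), cl)
  a <- add_gaussian_noise(cl, 0.01, 1)
  b <- add_gaussian_noise(cl, 0.01, 2)
  expect_false(identical(a$points, b$points))
  expect_identical(add_gaussian_noise(cl, 0.01, 1)$points, a$points)

  big <- point_cloud(matrix(0, 334000, 3), frame = "normalized")
  eps <- add_gaussian_noise(big, 0.01, 9)$points
  expect_lt(abs(sd(as.vector(eps)) - 0.01), 2e-4)
  expect_lt(abs(mean(as.vector(eps))), 2e-4)
})

test_that("landmarks come from cropped-out regions via farthest point sampling", {
  set.seed(17)
  src <- matrix(runif(90), ncol = 3)
  visible <- 1:20
  lm <- select_landmarks(src, src + 0.1, visible, n = 5)
  expect_length(lm$indices, 5)
  expect_length(intersect(lm$indices, visible), 0)
  expect_equal(lm$target, lm$source + 0.1)

  cropped <- setdiff(seq_len(30), visible)
  oracle <- fps_bruteforce(src[cropped, , drop = FALSE], 5, 1)
  expect_equal(lm$indices, cropped[oracle])
  expect_error(select_landmarks(src, src, 1:28, n = 5), "only 2")
})

test_that("default pipeline yields the 3500-source / 525-target contract", {
  pair <- default_pair()
  expect_equal(n_points(pair$source), 3500)
  expect_equal(n_points(pair$target), 525)
  expect_equal(sum(pair$overlap_labels), n_points(pair$target))
  expect_length(pair$correspondence, 525)
  expect_false(any(duplicated(pair$correspondence)))  # injective
  expect_true(all(pair$correspondence >= 1 & pair$correspondence <= 3500))
  expect_length(intersect(pair$landmark_indices, pair$correspondence), 0)
  expect_true(all(abs(pair$source$points) <= 1 + 1e-12))
})

test_that("pair generation is bit-reproducible from its seed", {
  mesh <- phantom_mesh()
  cfg <- generation_config(n_source_points = 600, arap_iters = 4)
  p1 <- generate_pair(mesh, cfg, seed = 9)
  p2 <- generate_pair(mesh, cfg, seed = 9)
  expect_identical(p1, p2)
  p3 <- generate_pair(mesh, cfg, seed = 10)
  expect_false(identical(p1$target$points, p3$target$points))
})

test_that("undoing the ground-truth transform recovers exact correspondences", {
  mesh <- phantom_mesh()
  cfg <- generation_config(n_source_points = 800, deform_max = 0, noise_sigma = 0)
  pair <- generate_pair(mesh, cfg, seed = 3)
  back <- apply_rigid(pair$target, invert_rigid(pair$gt_transform))
  err <- sqrt(rowSums((back$points - pair$source$points[pair$correspondence, ])^2))
  expect_lt(max(err), 1e-9)
  # landmarks coincide too once the ground truth is undone
  lm_back <- apply_rigid(pair$landmarks_target, invert_rigid(pair$gt_transform))
  expect_lt(max(abs(lm_back - pair$landmarks_source)), 1e-9)
})

test_that("TRE at the ground truth depends only on the deformation", {
  mesh <- phantom_mesh()
  cfg_a <- generation_config(n_source_points = 800)
  cfg_b <- generation_config(n_source_points = 800, rot_max = 5, trans_max = 5)
  pa <- generate_pair(mesh, cfg_a, seed = 21)
  pb <- generate_pair(mesh, cfg_b, seed = 21)
  tre_a <- target_registration_error(pa$landmarks_source, pa$landmarks_target,
                                     pa$gt_transform, pa$norm_map)
  tre_b <- target_registration_error(pb$landmarks_source, pb$landmarks_target,
                                     pb$gt_transform, pb$norm_map)
  expect_gt(tre_a, 0)
  expect_equal(tre_a, tre_b, tolerance = 1e-9)

  cfg_0 <- generation_config(n_source_points = 800, deform_max = 0)
  p0 <- generate_pair(mesh, cfg_0, seed = 21)
  expect_lt(target_registration_error(p0$landmarks_source, p0$landmarks_target,
                                      p0$gt_transform, p0$norm_map), 1e-9)
})

test_that("manifests enumerate the right pair counts with distinct seeds", {
  man_test <- dataset_manifest(c("liver01", "liver02"), 50)
  expect_equal(nrow(man_test), 100)
  man_train <- dataset_manifest(sprintf("liver%02d", 3:20), 560)
  expect_equal(nrow(man_train), 10080)
  expect_false(any(duplicated(man_train$seed)))
  expect_false(any(duplicated(man_test$path)))
})

test_that("pair archives survive the disk round trip", {
  mesh <- phantom_mesh()
  cfg <- generation_config(n_source_points = 400, arap_iters = 3)
  pair <- generate_pair(mesh, cfg, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".json.gz")
  write_pair_archive(pair, tmp)
  back <- read_pair_archive(tmp)
  expect_equal(back$source$points, pair$source$points, tolerance = 1e-12)
  expect_equal(back$target$points, pair$target$points, tolerance = 1e-12)
  expect_equal(back$gt_transform$rotation, pair$gt_transform$rotation,
               tolerance = 1e-12)
  expect_identical(back$correspondence, pair$correspondence)
  expect_identical(back$overlap_labels, pair$overlap_labels)
  expect_equal(back$norm_map$scale, pair$norm_map$scale)
})

test_that("generate_dataset writes archives and a manifest", {
  mesh <- phantom_mesh()
  cfg <- generation_config(n_source_points = 400, arap_iters = 3)
  tmp <- withr::local_tempdir()
  man <- generate_dataset(list(ph = mesh), 2, cfg, out_dir = tmp)
  expect_equal(nrow(man), 2)
  expect_true(all(is.na(man$error)))
  expect_true(all(file.exists(file.path(tmp, man$path))))
  expect_true(file.exists(file.path(tmp, "manifest.json")))
  back <- read_pair_archive(file.path(tmp, man$path[1]))
  regen <- generate_pair(mesh, cfg, man$seed[1])
  expect_equal(back$target$points, regen$target$points, tolerance = 1e-12)
})
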