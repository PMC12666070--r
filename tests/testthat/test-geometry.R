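test_that("PLY and OBJ meshes load with preserved structure", {
  tmp <- withr::local_tempdir()
  # minimal ASCII PLY: one triangle
  ply <- file.path(tmp, "tri.ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0",
               "3 0 1 2"), ply)
  m <- load_mesh(ply)
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 1)
  expect_equal(m$faces[1, ], c(1L, 2L, 3L))

  # OBJ with 1-based indices
  obj <- file.path(tmp, "tri.obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), obj)
  mo <- load_mesh(obj)
  expect_equal(mo$faces[1, ], c(1L, 2L, 3L))
  expect_equal(mo$vertices, m$vertices)

  # binary round trip is lossless
  mesh <- phantom_mesh()
  out <- file.path(tmp, "phantom.ply")
  save_mesh(mesh, out)
  back <- load_mesh(out)
  expect_identical(back$vertices, mesh$vertices)
  expect_identical(back$faces, mesh$faces)

  # cloud round trip with normals, both encodings
  cloud <- estimate_normals(sample_surface_points(mesh, 200, seed = 1), k = 10)
  for (bin in c(TRUE, FALSE)) {
    cp <- file.path(tmp, paste0("cloud", bin, ".ply"))
    write_cloud(cloud, cp, binary = bin)
    rc <- read_cloud(cp)
    expect_equal(rc$points, cloud$points, tolerance = 1e-12)
    expect_equal(rc$normals, cloud$normals, tolerance = 1e-12)
  }

  expect_error(load_mesh(file.path(tmp, "missing.ply")), "not found")
  bad <- file.path(tmp, "bad.ply")
  writeLines(c("not a ply"), bad)
  expect_error(load_mesh(bad), "magic|invalid")
})

test_that("surface sampling is area-weighted, on-plane and seeded", {
  sq <- unit_square_mesh()
  cl <- sample_surface_points(sq, 1e5, seed = 3, with_barycentric = TRUE)
  frac <- mean(attr(cl, "face") == 1L)
  expect_lt(abs(frac - 0.5), 0.01)
  expect_true(all(abs(cl$points[, 3]) < 1e-9))  # face planes are z = 0

  expect_equal(n_points(sample_surface_points(phantom_mesh(), 3500, seed = 0)), 3500)
  a <- sample_surface_points(phantom_mesh(), 100, seed = 5)
  b <- sample_surface_points(phantom_mesh(), 100, seed = 5)
  expect_identical(a$points, b$points)
  expect_error(sample_surface_points(sq, 3, seed = 0), ">= 4")
})

test_that("normal estimation recovers analytic normals", {
  set.seed(11)
  dirs <- matrix(rnorm(7500), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sph <- estimate_normals(point_cloud(dirs), k = 20)
  cosang <- abs(rowSums(sph$normals * dirs))
  expect_gte(mean(cosang > cos(5 * pi / 180)), 0.99)
  expect_true(all(abs(sqrt(rowSums(sph$normals^2)) - 1) < 1e-6))
  # outward orientation: radial dot normal positive on a sphere
  expect_true(all(rowSums(sph$normals * dirs) > 0))

  plane <- cbind(matrix(runif(400), ncol = 2), 0)
  pn <- estimate_normals(point_cloud(plane), k = 10, orient = "none")
  expect_true(all(abs(abs(pn$normals[, 3]) - 1) < 1e-6))
  expect_error(estimate_normals(point_cloud(plane[1:5, ]), k = 10), "fewer")
})

test_that("isotropic normalization maps the widest axis to [-1, 1]", {
  set.seed(4)
  box <- cbind(runif(2000, 0, 200), runif(2000, 0, 100), runif(2000, 0, 80))
  box <- rbind(box, c(0, 0, 0), c(200, 100, 80))  # pin the exact extremes
  nz <- normalize_isotropic(point_cloud(box))
  expect_equal(nz$map$scale, 100)
  expect_equal(nz$map$offset, c(100, 50, 40))
  expect_equal(range(nz$cloud$points[, 1]), c(-1, 1), tolerance = 1e-9)
  expect_true(all(abs(nz$cloud$points) <= 1 + 1e-12))
  back <- map_to_metric(nz$cloud, nz$map)
  expect_equal(back$points, box, tolerance = 1e-9)

  sym <- point_cloud(rbind(c(-1, -1, -1), c(1, 1, 1), c(0.3, -0.2, 0)))
  id <- normalize_isotropic(sym)
  expect_equal(id$map$scale, 1)
  expect_equal(id$map$offset, c(0, 0, 0))

  expect_error(normalize_isotropic(point_cloud(matrix(1, 5, 3))), "degenerate")
})

test_that("reference normalization uses only the complete cloud's map", {
  set.seed(9)
  comp <- matrix(runif(600, 0, 100), ncol = 3)
  comp <- rbind(comp, c(0, 0, 0), c(100, 100, 100))
  part_idx <- sample(nrow(comp), 40)
  nz <- normalize_with_reference(point_cloud(comp), point_cloud(comp[part_idx, ]))
  expect_equal(nz$partial$points, nz$complete$points[part_idx, ], tolerance = 1e-12)
  expect_equal(map_to_normalized(matrix(c(50, 50, 50), 1), nz$map), matrix(0, 1, 3))
  # points outside the reference box may exceed [-1, 1]: no clipping
  out <- normalize_with_reference(point_cloud(comp), point_cloud(matrix(c(150, 0, 0), 1)))
  expect_gt(max(out$partial$points), 1)
})

test_that("rigid transforms form a group and preserve distances", {
  cl <- point_cloud(matrix(rnorm(300), ncol = 3))
  expect_equal(apply_rigid(cl, rigid_transform())$points, cl$points)
  set.seed(21)
  for (rep in 1:10) {
    Tr <- random_rigid()
    moved <- apply_rigid(cl, Tr)
    back <- apply_rigid(moved, invert_rigid(Tr))
    expect_equal(back$points, cl$points, tolerance = 1e-12)
    d0 <- dist(cl$points[1:20, ])
    d1 <- dist(moved$points[1:20, ])
    expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)
    expect_equal(det(invert_rigid(Tr)$rotation), 1, tolerance = 1e-12)
  }
  Tz <- rigid_transform(axis_angle_matrix(c(0, 0, 1), 90), c(1, 0, 0))
  expect_equal(as.vector(apply_rigid(matrix(c(1, 0, 0), 1), invert_rigid(Tz))),
               c(0, 0, 0), tolerance = 1e-12)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "det")
})

test_that("farthest point sampling matches the exhaustive greedy oracle", {
  line <- cbind(0:10, 0, 0)
  expect_equal(farthest_point_sampling(line, 3, start = 1), c(1L, 11L, 6L))
  perm <- farthest_point_sampling(line, 11, start = 1)
  expect_setequal(perm, 1:11)
  expect_error(farthest_point_sampling(line, 12, 1), "exceeds")

  set.seed(31)
  for (rep in 1:15) {
    n_pts <- sample(4:12, 1)
    pts <- matrix(runif(n_pts * 3), ncol = 3)
    n_sel <- sample(2:n_pts, 1)
    st <- sample(n_pts, 1)
    expect_equal(farthest_point_sampling(pts, n_sel, st),
                 as.integer(fps_bruteforce(pts, n_sel, st)))
  }

  # max-min optimality against random subsets
  set.seed(32)
  pts <- matrix(runif(150), ncol = 3)
  sel <- farthest_point_sampling(pts, 8, 1)
  min_d <- min(dist(pts[sel, ]))
  rand_min <- replicate(100, min(dist(pts[sample(50, 8), ])))
  expect_true(all(min_d >= rand_min - 1e-12))
})

test_that("rigid transforms survive the JSON round trip", {
  tmp <- withr::local_tempfile(fileext = ".json")
  set.seed(5)
  Tr <- random_rigid()
  write_transform_json(Tr, tmp)
  back <- read_transform_json(tmp)
  expect_equal(back$rotation, Tr$rotation, tolerance = 1e-15)
  expect_equal(back$translation, Tr$translation, tolerance = 1e-15)
})
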