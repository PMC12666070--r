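test_that("weighted Kabsch-Umeyama recovers exact rigid transforms", {
  set.seed(41)
  for (rep in 1:10) {
    src <- matrix(rnorm(60), ncol = 3)
    Tr <- random_rigid()
    tgt <- apply_rigid(src, Tr)
    fit <- weighted_kabsch_umeyama(src, tgt)
    expect_equal(fit$rotation, Tr$rotation, tolerance = 1e-10)
    expect_equal(fit$translation, Tr$translation, tolerance = 1e-10)
    # uniform weights coincide with the classic unweighted Umeyama oracle
    noisy <- tgt + matrix(rnorm(60, 0, 0.05), ncol = 3)
    fit_u <- weighted_kabsch_umeyama(src, noisy)
    oracle <- umeyama_oracle(src, noisy)
    expect_equal(fit_u$rotation, oracle$R, tolerance = 1e-10)
    expect_equal(fit_u$translation, oracle$t, tolerance = 1e-10)
  }
})

test_that("zero-weight outliers do not influence the Kabsch solution", {
  set.seed(42)
  src <- matrix(rnorm(45), ncol = 3)
  Tr <- random_rigid()
  tgt <- apply_rigid(src, Tr)
  src_o <- rbind(src, matrix(rnorm(9, 0, 10), ncol = 3))
  tgt_o <- rbind(tgt, matrix(rnorm(9, 0, 10), ncol = 3))
  w <- c(rep(1, 15), rep(0, 3))
  fit <- weighted_kabsch_umeyama(src_o, tgt_o, w)
  ref <- weighted_kabsch_umeyama(src, tgt)
  expect_equal(fit$rotation, ref$rotation, tolerance = 1e-12)
  expect_equal(fit$translation, ref$translation, tolerance = 1e-12)

  id <- weighted_kabsch_umeyama(src, src)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-12)

  line <- cbind(seq_len(5), 0, 0)
  expect_error(weighted_kabsch_umeyama(line, line + 1), "collinear")
  expect_error(weighted_kabsch_umeyama(src[1:2, ], src[1:2, ]), "K >= 3")
})

test_that("ICP recovers small rigid offsets and respects its contracts", {
  set.seed(43)
  src <- point_cloud(matrix(rnorm(900, 0, 0.5), ncol = 3), frame = "normalized")
  Tr <- rigid_transform(axis_angle_matrix(c(0, 1, 0), 5), c(0.05, -0.02, 0.03))
  tgt <- apply_rigid(src, Tr)
  res <- icp_register(src, tgt, threshold = 1e-8)
  expect_true(transform_close(res$transform, Tr, 0.1, 0.001))

  same <- icp_register(src, src)
  expect_equal(same$transform$rotation, diag(3), tolerance = 1e-9)
  expect_lt(same$final_residual, 1e-9)
  expect_lte(same$n_iterations, 2)

  none <- icp_register(src, tgt, max_iter = 0)
  expect_equal(none$n_iterations, 0)
  expect_equal(none$transform$rotation, diag(3))

  expect_true(all(diff(res$trace) <= 1e-12))
})

test_that("rigid CPD recovers small transforms with monotone likelihood", {
  set.seed(44)
  src <- point_cloud(matrix(rnorm(600, 0, 0.5), ncol = 3), frame = "normalized")
  Tr <- rigid_transform(axis_angle_matrix(c(1, 1, 0), 8), c(0.04, 0.02, -0.03))
  tgt <- apply_rigid(src, Tr)
  res <- cpd_rigid_register(src, tgt, tol = 1e-8)
  expect_true(transform_close(res$transform, Tr, 0.5, 0.005))
  expect_true(all(diff(res$trace) >= -1e-6 * abs(res$trace[1])))

  same <- cpd_rigid_register(src, src)
  expect_true(transform_close(same$transform, rigid_transform(), 1e-4, 1e-6))
})

test_that("CPD E-step posteriors are correctly normalized", {
  set.seed(45)
  Y <- matrix(rnorm(30), ncol = 3)
  X <- matrix(rnorm(21), ncol = 3)
  sigma2 <- 0.5; w <- 0.2
  es <- liverbench:::cpp_cpd_estep(Y, X, sigma2, w)
  # direct dense computation of the posterior matrix
  M <- nrow(Y); N <- nrow(X)
  num <- exp(-as.matrix(pracma::distmat(Y, X))^2 / (2 * sigma2))
  cc <- (2 * pi * sigma2)^1.5 * w / (1 - w) * M / N
  P <- sweep(num, 2, colSums(num) + cc, "/")
  expect_equal(as.numeric(es$P1), rowSums(P), tolerance = 1e-12)
  expect_equal(as.numeric(es$Pt1), colSums(P), tolerance = 1e-12)
  expect_equal(es$PX, P %*% X, tolerance = 1e-12, ignore_attr = TRUE)
  # per-target posteriors + outlier mass sum to one
  outlier <- cc / (colSums(num) + cc)
  expect_equal(colSums(P) + outlier, rep(1, N), tolerance = 1e-12)
})

test_that("GMM L2 cross term matches Monte-Carlo integration", {
  set.seed(46)
  a <- matrix(c(0.2, -0.1, 0.3), 1)
  b <- matrix(c(-0.4, 0.5, 0.1), 1)
  sigma <- 0.35
  closed <- gmm_l2_cross_term(a, b, sigma)
  # MC estimate of integral f*g = E_{x~f}[g(x)]
  x <- sweep(matrix(rnorm(3e6, 0, sigma), ncol = 3), 2, a[1, ], "+")
  g <- exp(-rowSums(sweep(x, 2, b[1, ])^2) / (2 * sigma^2)) / (2 * pi * sigma^2)^1.5
  expect_lt(abs(mean(g) - closed) / closed, 0.01)
})

test_that("GMM L2 self-alignment is minimal at the identity", {
  set.seed(47)
  cl <- matrix(rnorm(150, 0, 0.5), ncol = 3)
  sigma <- 0.2
  self_val <- gmm_l2_cross_term(cl, cl, sigma)
  vals <- replicate(100, {
    gmm_l2_cross_term(apply_rigid(cl, random_rigid(0.3)), cl, sigma)
  })
  expect_true(all(self_val >= vals))
})

test_that("GMMReg recovers small rigid offsets", {
  set.seed(48)
  src <- point_cloud(matrix(rnorm(450, 0, 0.5), ncol = 3), frame = "normalized")
  Tr <- rigid_transform(axis_angle_matrix(c(0, 0, 1), 7), c(0.03, -0.04, 0.02))
  tgt <- apply_rigid(src, Tr)
  res <- gmmreg_register(src, tgt)
  expect_true(transform_close(res$transform, Tr, 1, 0.01))
})

test_that("FPFH descriptors are rigid-invariant and match correctly", {
  set.seed(49)
  mesh <- phantom_mesh()
  src <- estimate_normals(
    normalize_isotropic(sample_surface_points(mesh, 700, seed = 2))$cloud, 15)

  d0 <- liverbench:::fpfh_descriptors(src, radius = 0.3)
  Tr <- random_rigid(0.2)
  moved <- apply_rigid(src, Tr)
  d1 <- liverbench:::fpfh_descriptors(moved, radius = 0.3)
  # rigid-invariant up to knife edges in the standard pair-feature source
  # convention (a handful of near-symmetric pairs can swap roles)
  expect_lt(max(abs(d1 - d0)), 0.01)
  expect_lt(mean(abs(d1 - d0)), 1e-4)

  # self-matching is the identity
  self <- descriptor_correspondences(src, src, radius = 0.3)
  expect_equal(self$source_idx, self$target_idx)
  expect_length(self, n_points(src))

  # rigidly moved contiguous subset: most mutual matches are ground-truth
  # correct (interior points keep their exact neighbourhoods)
  keep <- which(src$points[, 1] > 0)
  part <- point_cloud(moved$points[keep, ], moved$normals[keep, ], "normalized")
  corr <- descriptor_correspondences(src, part, radius = 0.15)
  expect_gt(length(corr), 100)
  acc <- mean(corr$source_idx == keep[corr$target_idx])
  expect_gte(acc, 0.8)

  expect_error(descriptor_correspondences(src, src, radius = 1e-6), "too small")
})

test_that("RANSAC pose estimation is robust to outlier correspondences", {
  set.seed(50)
  src_pts <- matrix(rnorm(450, 0, 0.5), ncol = 3)
  Tr <- random_rigid(0.3)
  tgt_pts <- apply_rigid(src_pts, Tr)
  src <- point_cloud(src_pts, frame = "normalized")
  tgt <- point_cloud(tgt_pts, frame = "normalized")

  good <- correspondence_set(1:100, 1:100)
  res_exact <- ransac_pose(src, tgt, good, n_iters = 300, refine = FALSE)
  expect_equal(length(res_exact$correspondences), 100)
  expect_lt(res_exact$final_residual, 1e-9)
  expect_true(transform_close(res_exact$transform, Tr, 1e-4, 1e-6))

  # 100 inliers + 50 shuffled outliers
  out_t <- sample(101:150)
  corr <- correspondence_set(c(1:100, 101:150), c(1:100, out_t))
  res <- ransac_pose(src, tgt, corr, n_iters = 500, refine = FALSE)
  expect_gte(length(res$correspondences), 100)
  expect_true(transform_close(res$transform, Tr, 0.5, 0.005))

  # minimal case: 3 exact correspondences in general position
  tri <- correspondence_set(c(1, 5, 9), c(1, 5, 9))
  res3 <- ransac_pose(src, tgt, tri, n_iters = 10, refine = FALSE)
  expect_true(transform_close(res3$transform, Tr, 1e-4, 1e-6))

  # order permutation with the same seed policy changes nothing material
  perm <- sample(150)
  corr_p <- correspondence_set(corr$source_idx[perm], corr$target_idx[perm])
  res_p <- ransac_pose(src, tgt, corr_p, n_iters = 500, refine = FALSE)
  expect_true(transform_close(res_p$transform, res$transform, 1e-3, 1e-5))

  expect_error(ransac_pose(src, tgt, correspondence_set(1:2, 1:2)), "at least 3")
})

test_that("solvers are equivariant under a common frame rotation", {
  set.seed(51)
  src <- point_cloud(matrix(rnorm(600, 0, 0.5), ncol = 3), frame = "normalized")
  Tr <- rigid_transform(axis_angle_matrix(c(1, 0, 1), 6), c(0.03, 0.01, -0.02))
  tgt <- apply_rigid(src, Tr)
  Q <- rigid_transform(random_rotation(), c(0.1, -0.2, 0.05))
  src_q <- apply_rigid(src, Q)
  tgt_q <- apply_rigid(tgt, Q)
  base <- icp_register(src, tgt, threshold = 1e-9)
  conj <- icp_register(src_q, tgt_q, threshold = 1e-9)
  expected <- compose_rigid(Q, compose_rigid(base$transform, invert_rigid(Q)))
  expect_true(transform_close(conj$transform, expected, 1e-3, 1e-5))
})

test_that("overlap head fixes partial scores at one and squashes features", {
  params <- overlap_head_params(w1 = c(0.5, -0.2), b1 = 0)
  z <- overlap_head(matrix(0, 4, 2), params, n_partial = 7)
  expect_equal(z$complete, rep(0.5, 4))
  expect_identical(z$partial, rep(1, 7))

  set.seed(52)
  for (rep in 1:5) {
    f <- matrix(rnorm(60, sd = 10), ncol = 3)
    p <- overlap_head_params(rnorm(3), rnorm(1))
    s <- overlap_head(f, p, n_partial = rep)
    expect_true(all(s$complete > 0 & s$complete < 1))
    expect_identical(s$partial, rep(1, rep))
  }

  # monotone in the linear response
  grid <- matrix(seq(-50, 50, length.out = 101), ncol = 1)
  s <- overlap_head(grid, overlap_head_params(1, 0), 1)$complete
  expect_true(all(diff(s) >= 0))
  expect_lt(max(s), 1)

  expect_error(overlap_head(matrix(Inf, 1, 1), overlap_head_params(1), 1), "finite")
  expect_error(overlap_head(matrix(0, 2, 3), overlap_head_params(c(1, 2)), 1),
               "does not match")
})

test_that("training losses satisfy their closed-form identities", {
  set.seed(53)
  K <- 12
  gt <- matrix(rnorm(K * 3), ncol = 3)
  fa <- diag(K) * 3  # well-separated features
  fb <- fa
  labels <- rep(c(1, 0), each = K / 2)
  perfect <- compute_losses(gt, gt, overlap_scores = pmin(labels + 1e-9, 1 - 1e-9),
                            features_a = fa, features_b = fb,
                            gt_correspondence = 1:K, gt_overlap = labels)
  expect_lt(perfect$registration, 1e-12)
  expect_equal(perfect$feature, 0, tolerance = 1e-9)
  expect_lt(perfect$overlap, 1e-6)

  pred <- gt + 0.1
  scores <- runif(K)
  l1 <- compute_losses(pred, gt, scores, fa, fb, 1:K, labels)
  l2 <- compute_losses(gt + 0.2, gt, scores, fa, fb, 1:K, labels)
  expect_equal(l2$registration, 2 * l1$registration, tolerance = 1e-12)

  half <- compute_losses(gt, gt, rep(0.5, K), fa, fb, 1:K, labels)
  expect_equal(half$overlap, log(2), tolerance = 1e-12)

  expect_error(compute_losses(gt[1:3, ], gt, scores, fa, fb, 1:K, labels),
               "mismatch")
})
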