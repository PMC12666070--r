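#' Correspondence set between two clouds
#'
#' @param source_idx,target_idx parallel integer vectors of matched indices.
#' @param weights per-pair confidence scores in `[0, 1]` (default 1).
#' @return an object of class `correspondence_set`.
#' @export
correspondence_set <- function(source_idx, target_idx, weights = NULL) {
  source_idx <- as.integer(source_idx); target_idx <- as.integer(target_idx)
  if (length(source_idx) != length(target_idx)) stop("index vectors must have equal length")
  if (is.null(weights)) weights <- rep(1, length(source_idx))
  if (length(weights) != length(source_idx)) stop("weights length mismatch")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  structure(list(source_idx = source_idx, target_idx = target_idx,
                 weights = as.numeric(weights)),
            class = "correspondence_set")
}

#' @exportS3Method base::print
print.correspondence_set <- function(x, ...) {
  cat(sprintf("<correspondence_set: %d pairs>\n", length(x$source_idx)))
  invisible(x)
}

#' @export
length.correspondence_set <- function(x) length(x$source_idx)

registration_result <- function(transform, n_iterations, final_residual,
                                correspondences = NULL, converged = TRUE,
                                flag = NA_character_, trace = NULL) {
  structure(list(transform = transform, n_iterations = as.integer(n_iterations),
                 final_residual = final_residual,
                 correspondences = correspondences, converged = converged,
                 flag = flag, trace = trace),
            class = "registration_result")
}

#' @exportS3Method base::print
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result: %d iterations, residual %.3g%s>\n",
              x$n_iterations, x$final_residual,
              if (is.na(x$flag)) "" else paste0(", flag=", x$flag)))
  invisible(x)
}

#' Weighted Kabsch-Umeyama rigid alignment
#'
#' Closed-form minimizer of \eqn{\sum_i w_i \|R s_i + t - t_i\|^2}: weighted
#' centroids, SVD of the weighted cross-covariance and a determinant-sign
#' correction enforcing \eqn{\det(R) = +1}. No scale is estimated.
#'
#' @param src_points,tgt_points K x 3 matrices of paired points (K >= 3).
#' @param weights K non-negative weights with positive sum (default uniform).
#' @return a `rigid_transform` mapping `src_points` onto `tgt_points`.
#' @export
weighted_kabsch_umeyama <- function(src_points, tgt_points, weights = NULL) {
  src_points <- as_coord_matrix(src_points, "src_points")
  tgt_points <- as_coord_matrix(tgt_points, "tgt_points")
  K <- nrow(src_points)
  if (K < 3 || nrow(tgt_points) != K) stop("need K >= 3 paired points")
  if (is.null(weights)) weights <- rep(1, K)
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cs <- colSums(src_points * w)
  ct <- colSums(tgt_points * w)
  S <- sweep(src_points, 2, cs)
  T_ <- sweep(tgt_points, 2, ct)
  H <- crossprod(S * w, T_)  # sum_i w_i s_i t_i^T
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate geometry: weighted correspondence support is (near-)collinear")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(Rm, ct - as.numeric(Rm %*% cs))
}

#' Iterative closest point rigid registration
#'
#' Identity-initialized point-to-point ICP: each iteration pairs every target
#' point with its nearest neighbour in the transformed source (the sparse
#' partial cloud drives the pairing, avoiding many-to-one collapse from the
#' dense side) and updates the pose by the closed-form SVD solution. Stops
#' when the residual improvement falls below `threshold` or after `max_iter`
#' iterations; the recorded residual sequence is non-increasing.
#'
#' @param source,target `point_cloud` objects in the same frame.
#' @param threshold convergence threshold on the RMS-residual change.
#' @param max_iter maximum number of iterations.
#' @param init optional initial `rigid_transform` (identity by default).
#' @return a `registration_result`.
#' @export
icp_register <- function(source, target, threshold = 0.001, max_iter = 30,
                         init = rigid_transform()) {
  sp <- source$points; tp <- target$points
  if (!nrow(sp) || !nrow(tp)) stop("clouds must be non-empty")
  Tcur <- init
  residuals <- numeric(0)
  prev <- Inf
  flag <- NA_character_
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    moved <- apply_rigid(sp, Tcur)
    nn <- cpp_knn(tp, moved, 1L)
    idx <- nn$idx[, 1]
    Tnew <- tryCatch(weighted_kabsch_umeyama(sp[idx, , drop = FALSE], tp),
                     error = function(e) NULL)
    if (is.null(Tnew)) { flag <- "degenerate_correspondences"; it <- it - 1; break }
    Tcur <- Tnew
    res <- sqrt(mean(rowSums((apply_rigid(sp[idx, , drop = FALSE], Tcur) - tp)^2)))
    residuals <- c(residuals, res)
    if (prev - res < threshold) break
    prev <- res
  }
  final <- if (length(residuals)) residuals[length(residuals)] else {
    moved <- apply_rigid(sp, Tcur)
    nn <- cpp_knn(tp, moved, 1L)
    sqrt(mean(nn$dist[, 1]^2))
  }
  registration_result(Tcur, it, final, converged = it < max_iter || max_iter == 0,
                      flag = flag, trace = residuals)
}

#' Rigid coherent point drift registration
#'
#' Expectation-maximization over a Gaussian mixture whose centroids are the
#' (transformed) source points and whose data are the target points, with a
#' uniform outlier component of weight `outlier_w`. The M-step is the
#' closed-form rigid update (scale fixed at 1) plus the isotropic variance
#' update, so the negative log-likelihood is non-increasing per EM step.
#'
#' @param source,target `point_cloud` objects; source points act as the
#'   mixture centroids.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the log-likelihood change falls below `tol`.
#' @param outlier_w uniform-outlier mixing weight in `[0, 1)`.
#' @param sigma2_init initial mixture variance. The default (`NULL`) is the
#'   classic all-pairs variance; in the complete-to-partial regime that
#'   global initialization drags the full source's centre of mass onto the
#'   small target patch before local structure can engage, so a local scale
#'   (for example `(0.1 * target diameter)^2`) keeps the first E-steps
#'   neighbourhood-sized and preserves the identity-initialized basin.
#' @return a `registration_result` (transform maps source onto target).
#' @export
cpd_rigid_register <- function(source, target, max_iter = 50, tol = 0.001,
                               outlier_w = 0.1, sigma2_init = NULL) {
  Y <- source$points; X <- target$points
  M <- nrow(Y); N <- nrow(X)
  if (!M || !N) stop("clouds must be non-empty")
  Rm <- diag(3); tv <- c(0, 0, 0)
  sigma2 <- sigma2_init %||%
    ((N * sum(Y^2) + M * sum(X^2) - 2 * sum(colSums(X) * colSums(Y))) / (3 * M * N))
  ll_prev <- -Inf
  loglik <- numeric(0)
  flag <- NA_character_
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    TY <- sweep(Y %*% t(Rm), 2, tv, "+")
    es <- cpp_cpd_estep(TY, X, sigma2, outlier_w)
    es$P1 <- as.numeric(es$P1); es$Pt1 <- as.numeric(es$Pt1)
    loglik <- c(loglik, es$loglik)
    Np <- es$Np
    if (Np < .Machine$double.eps) { flag <- "all_outliers"; break }
    mu_x <- colSums(X * es$Pt1) / Np
    mu_y <- colSums(Y * es$P1) / Np
    Xhat_ss <- sum(es$Pt1 * rowSums(sweep(X, 2, mu_x)^2))
    Yhat <- sweep(Y, 2, mu_y)
    PXhat <- es$PX - outer(es$P1, mu_x)
    A <- crossprod(PXhat, Yhat)   # sum_mn p_mn xhat_n yhat_m^T
    sv <- svd(A)
    d <- sign(det(sv$u %*% t(sv$v)))
    Rm <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
    tv <- mu_x - as.numeric(Rm %*% mu_y)
    Yhat_ss <- sum(es$P1 * rowSums(Yhat^2))
    trAR <- sum(diag(crossprod(A, Rm)))
    sigma2 <- max((Xhat_ss - 2 * trAR + Yhat_ss) / (3 * Np), 0)
    if (sigma2 < 1e-12) { flag <- "variance_collapse"; break }
    if (abs(es$loglik - ll_prev) < tol) break
    ll_prev <- es$loglik
  }
  Tfinal <- rigid_transform(Rm, tv)
  moved <- apply_rigid(Y, Tfinal)
  nn <- cpp_knn(X, moved, 1L)
  registration_result(Tfinal, it, sqrt(mean(nn$dist[, 1]^2)),
                      converged = it < max_iter, flag = flag, trace = loglik)
}

#' Gaussian-mixture L2 rigid registration
#'
#' Both clouds are represented as isotropic, equal-weight Gaussian mixtures
#' (one component per point, shared bandwidth). The rigid parameters
#' (rotation vector + translation) minimize the closed-form L2 distance
#' between the mixtures; the self-correlation terms are rigid-invariant, so
#' only the cross-correlation is optimized, by BFGS with analytic gradients
#' under a coarse-to-fine bandwidth schedule.
#'
#' @param source,target `point_cloud` objects.
#' @param bandwidths annealing schedule of mixture bandwidths; default is
#'   `c(0.5, 0.1)` times the target cloud's bounding-box diagonal.
#' @param n_components number of mixture components per cloud; defaults to
#'   the full point count (the target cloud's size for the target mixture).
#'   Smaller values subsample both clouds by farthest point sampling.
#' @param max_iter BFGS iteration cap per bandwidth stage.
#' @param init optional initial `rigid_transform`.
#' @return a `registration_result`.
#' @export
gmmreg_register <- function(source, target, bandwidths = NULL,
                            n_components = NULL, max_iter = 50,
                            init = rigid_transform()) {
  sp <- source$points; tp <- target$points
  if (!nrow(sp) || !nrow(tp)) stop("clouds must be non-empty")
  if (!is.null(n_components)) {
    if (n_components < nrow(sp)) sp <- sp[farthest_point_sampling(sp, n_components), ]
    if (n_components < nrow(tp)) tp <- tp[farthest_point_sampling(tp, n_components), ]
  }
  if (is.null(bandwidths)) {
    diam <- sqrt(sum(apply(tp, 2, function(v) diff(range(v)))^2))
    bandwidths <- c(0.5, 0.1) * diam
  }
  par <- c(rotation_log(init$rotation), init$translation)
  n_eval <- 0L
  flag <- NA_character_
  best_val <- Inf
  for (sg in bandwidths) {
    s2 <- sg^2
    fn <- function(p) {
      A <- sweep(sp %*% t(rotation_exp(p[1:3])), 2, p[4:6], "+")
      -cpp_gmm_l2_cross(A, tp, s2)$value
    }
    gr <- function(p) {
      Rm <- rotation_exp(p[1:3])
      A <- sweep(sp %*% t(Rm), 2, p[4:6], "+")
      g <- cpp_gmm_l2_cross(A, tp, s2)$grad
      gt_ <- colSums(g)
      gw <- vapply(1:3, function(k) {
        dR <- rotation_exp_deriv(p[1:3], Rm, k)
        sum(g * (sp %*% t(dR)))
      }, 0)
      -c(gw, gt_)
    }
    opt <- tryCatch(
      optim(par, fn, gr, method = "BFGS",
            control = list(maxit = max_iter, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) { flag <- "optimizer_failure"; break }
    par <- opt$par
    n_eval <- n_eval + opt$counts[1]
    best_val <- opt$value
  }
  Tfinal <- rigid_transform(rotation_exp(par[1:3]), par[4:6])
  registration_result(Tfinal, n_eval, best_val, converged = is.na(flag), flag = flag)
}

# Rotation vector (axis * angle, radians) <-> rotation matrix.
rotation_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew(w))
  axis_angle_matrix(w / th, th * 180 / pi)
}

rotation_log <- function(R) {
  th <- rotation_angle(R) * pi / 180
  if (th < 1e-9) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  ax * th
}

skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)

# dR/dw_k for the rotation-vector parametrization (Gallego & Yezzi form).
rotation_exp_deriv <- function(w, R, k) {
  th2 <- sum(w^2)
  e <- c(0, 0, 0); e[k] <- 1
  if (th2 < 1e-12) return(skew(e))
  v <- w[k] * w + cross3(w, as.numeric((diag(3) - R) %*% e))
  (skew(v) / th2) %*% R
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Closed-form L2 cross-correlation between two Gaussian mixtures
#'
#' Equal-weight isotropic mixtures with one component per row and shared
#' bandwidth `sigma` per mixture; the integral of the product of the two
#' densities. Exposed for testing against Monte-Carlo integration.
#'
#' @param a,b component-mean matrices (rows are means).
#' @param sigma per-mixture component standard deviation.
#' @return scalar value of the integral.
#' @export
gmm_l2_cross_term <- function(a, b, sigma) {
  cpp_gmm_l2_cross(as_coord_matrix(a, "a"), as_coord_matrix(b, "b"), sigma^2)$value
}

#' FPFH descriptor matching between two clouds
#'
#' Rotation-invariant fast point-feature histograms (33 bins) are computed at
#' every point of both clouds from `radius`-bounded neighbourhoods; matches
#' are mutual nearest neighbours in descriptor space with weights equal to
#' the normalized descriptor similarity. This non-learned correspondence
#' front end lets the correspondence-to-RANSAC pose path run without any
#' trained network.
#'
#' @param source,target `point_cloud` objects (normals estimated if absent).
#' @param radius neighbourhood radius in cloud units; the radius (not the
#'   cap) should govern the neighbourhood so descriptors stay comparable
#'   across clouds of different density.
#' @param k_max cap on neighbours per point within the radius.
#' @return a `correspondence_set` (source index, target index, weight).
#' @export
descriptor_correspondences <- function(source, target, radius = 0.3, k_max = 60) {
  f_s <- fpfh_descriptors(source, radius, k_max)
  f_t <- fpfh_descriptors(target, radius, k_max)
  st <- cpp_knn(f_t, f_s, 1L)   # for each target descriptor, nearest source
  ts <- cpp_knn(f_s, f_t, 1L)
  src_of_t <- st$idx[, 1]
  tgt_of_s <- ts$idx[, 1]
  mutual <- which(tgt_of_s[src_of_t] == seq_along(src_of_t))
  if (!length(mutual)) return(correspondence_set(integer(0), integer(0)))
  d <- st$dist[mutual, 1]
  sim <- 1 / (1 + d)
  correspondence_set(src_of_t[mutual], mutual, sim / max(sim))
}

fpfh_descriptors <- function(cloud, radius, k_max = 60) {
  if (is.null(cloud$normals)) cloud <- estimate_normals(cloud, k = min(20, n_points(cloud) - 1))
  pts <- cloud$points
  k <- min(k_max, nrow(pts))
  nn <- cpp_knn(pts, pts, as.integer(k))
  out_of_range <- nn$dist > radius
  # neighbours beyond the radius are redirected to the point itself (skipped)
  for (col in seq_len(ncol(nn$idx))) {
    nn$idx[out_of_range[, col], col] <- which(out_of_range[, col])
  }
  n_isolated <- sum(rowSums(!out_of_range) <= 1)  # self only
  if (n_isolated > nrow(pts) / 2) {
    stop("radius ", radius, " too small: ", n_isolated, " points have empty neighbourhoods")
  }
  cpp_fpfh(pts, cloud$normals, nn$idx, nn$dist)
}

#' RANSAC pose estimation from correspondences
#'
#' Samples 3-correspondence hypotheses solved by the Kabsch closed form;
#' a correspondence is an inlier when its post-transform distance is below
#' `max_corr_dist`. The model with the most inliers wins (ties broken by
#' lower inlier residual); with `refine = TRUE` the pose is re-estimated on
#' all inliers and polished by ICP started from the RANSAC pose.
#'
#' @param source,target `point_cloud` objects the correspondence indices
#'   refer to.
#' @param corrs a `correspondence_set` with at least 3 pairs.
#' @param max_corr_dist inlier distance threshold (cloud units).
#' @param n_iters number of sampled hypotheses.
#' @param refine polish the winning pose with ICP.
#' @param seed seed for hypothesis sampling.
#' @return a `registration_result`; a failure to find >= 3 inliers returns
#'   the identity transform with flag `"ransac_failure"`.
#' @export
ransac_pose <- function(source, target, corrs, max_corr_dist = 0.05,
                        n_iters = 10000, refine = TRUE, seed = 0L) {
  K <- length(corrs)
  if (K < 3) stop("need at least 3 correspondences")
  sp <- source$points[corrs$source_idx, , drop = FALSE]
  tp <- target$points[corrs$target_idx, , drop = FALSE]
  picks <- withr::with_seed(seed, {
    matrix(replicate(n_iters, sample.int(K, 3)), ncol = 3, byrow = TRUE)
  })
  best_n <- 0L; best_res <- Inf; best_T <- NULL; best_inl <- NULL
  thr2 <- max_corr_dist^2
  for (i in seq_len(n_iters)) {
    id3 <- picks[i, ]
    Th <- tryCatch(weighted_kabsch_umeyama(sp[id3, ], tp[id3, ]),
                   error = function(e) NULL)
    if (is.null(Th)) next
    d2 <- rowSums((apply_rigid(sp, Th) - tp)^2)
    inl <- d2 < thr2
    n_in <- sum(inl)
    if (n_in < 3) next
    res <- sqrt(mean(d2[inl]))
    if (n_in > best_n || (n_in == best_n && res < best_res)) {
      best_n <- n_in; best_res <- res; best_T <- Th; best_inl <- inl
    }
  }
  if (is.null(best_T)) {
    return(registration_result(rigid_transform(), n_iters, Inf,
                               correspondences = corrs, converged = FALSE,
                               flag = "ransac_failure"))
  }
  Tfit <- tryCatch(weighted_kabsch_umeyama(sp[best_inl, , drop = FALSE],
                                           tp[best_inl, , drop = FALSE]),
                   error = function(e) best_T)
  if (refine) {
    icp <- icp_register(source, target, init = Tfit)
    Tfit <- icp$transform
    best_res <- icp$final_residual
  } else {
    d2 <- rowSums((apply_rigid(sp, Tfit) - tp)^2)
    best_res <- sqrt(mean(d2[d2 < thr2]))
  }
  registration_result(Tfit, n_iters, best_res,
                      correspondences = correspondence_set(
                        corrs$source_idx[best_inl], corrs$target_idx[best_inl],
                        corrs$weights[best_inl]),
                      converged = TRUE)
}

#' Overlap head parameters
#' @param w1 length-D weight vector.
#' @param b1 scalar bias.
#' @return an object of class `overlap_head_params`.
#' @export
overlap_head_params <- function(w1, b1 = 0) {
  w1 <- as.numeric(w1); b1 <- as.numeric(b1)
  if (!all(is.finite(w1)) || !is.finite(b1)) stop("parameters must be finite")
  structure(list(w1 = w1, b1 = b1), class = "overlap_head_params")
}

#' Complete-to-partial overlap head
#'
#' Per-point overlap scores for the complete cloud's keypoints are the
#' element-wise sigmoid of a linear map of the conditioned features,
#' `sigmoid(features %*% w1 + b1)`, each strictly inside (0, 1). Because the
#' partial cloud is by definition fully contained in the complete one,
#' every partial-cloud score is fixed to exactly 1 — predicting it would
#' only add estimator error.
#'
#' @param features K x D conditioned feature matrix for the complete cloud's
#'   keypoints.
#' @param params an `overlap_head_params` with `length(w1) == D`.
#' @param n_partial number of partial-cloud keypoints.
#' @return list with `complete` (K scores in (0,1)) and `partial`
#'   (`n_partial` ones).
#' @export
overlap_head <- function(features, params, n_partial) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite")
  if (ncol(features) != length(params$w1)) {
    stop("feature width ", ncol(features), " does not match parameter length ",
         length(params$w1))
  }
  z <- as.numeric(features %*% params$w1 + params$b1)
  s <- 1 / (1 + exp(-z))
  eps <- .Machine$double.eps
  s <- pmin(pmax(s, eps), 1 - eps / 2)
  list(complete = s, partial = rep(1, n_partial))
}

#' Training losses for overlap-guided correspondence registration
#'
#' Three components: (i) a registration loss — the overlap-confidence-
#' weighted mean absolute error between predicted transformed keypoint
#' positions and their ground truth; (ii) a conditioned-feature contrastive
#' loss — hinge terms pulling true-match feature pairs within `margin_pos`
#' and pushing non-matches beyond `margin_neg`; (iii) an overlap loss —
#' binary cross-entropy of the overlap scores against the overlap labels.
#'
#' @param pred_keypoints,gt_keypoints K x 3 matrices of predicted and
#'   ground-truth keypoint positions.
#' @param overlap_scores per-keypoint confidence in `[0, 1]` weighting the
#'   registration loss.
#' @param features_a,features_b conditioned feature matrices for the two
#'   clouds.
#' @param gt_correspondence for each row of `features_a`, the matching row
#'   of `features_b`, or `NA` when unmatched.
#' @param gt_overlap binary labels for `overlap_scores`.
#' @param loss_weights length-3 non-negative weights of the components.
#' @param margin_pos,margin_neg contrastive margins.
#' @return list with `total`, `registration`, `feature`, `overlap`.
#' @export
compute_losses <- function(pred_keypoints, gt_keypoints, overlap_scores,
                           features_a, features_b, gt_correspondence,
                           gt_overlap, loss_weights = c(1, 1, 1),
                           margin_pos = 0.1, margin_neg = 1.0) {
  pred_keypoints <- as.matrix(pred_keypoints); gt_keypoints <- as.matrix(gt_keypoints)
  if (!all(dim(pred_keypoints) == dim(gt_keypoints))) stop("keypoint shape mismatch")
  if (length(overlap_scores) != nrow(pred_keypoints)) stop("overlap score shape mismatch")
  if (any(loss_weights < 0)) stop("loss weights must be >= 0")
  ws <- sum(overlap_scores)
  l_reg <- if (ws > 0) {
    sum(overlap_scores * rowMeans(abs(pred_keypoints - gt_keypoints))) / ws
  } else 0

  fa <- as.matrix(features_a); fb <- as.matrix(features_b)
  matched <- which(!is.na(gt_correspondence))
  l_feat <- 0
  if (length(matched)) {
    pos_d <- sqrt(rowSums((fa[matched, , drop = FALSE] -
                           fb[gt_correspondence[matched], , drop = FALSE])^2))
    hinge_pos <- mean(pmax(0, pos_d - margin_pos))
    D <- sqrt(outer(rowSums(fa[matched, , drop = FALSE]^2), rowSums(fb^2), "+") -
              2 * fa[matched, , drop = FALSE] %*% t(fb))
    D[cbind(seq_along(matched), gt_correspondence[matched])] <- NA
    hinge_neg <- mean(pmax(0, margin_neg - D), na.rm = TRUE)
    l_feat <- hinge_pos + hinge_neg
  }

  if (length(gt_overlap) != length(overlap_scores)) stop("overlap label shape mismatch")
  eps <- 1e-12
  s <- pmin(pmax(overlap_scores, eps), 1 - eps)
  l_ovl <- -mean(gt_overlap * log(s) + (1 - gt_overlap) * log(1 - s))

  list(total = sum(loss_weights * c(l_reg, l_feat, l_ovl)),
       registration = l_reg, feature = l_feat, overlap = l_ovl)
}
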