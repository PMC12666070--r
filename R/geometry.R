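#' Point cloud container
#'
#' An ordered set of 3D points with optional unit normals and a frame tag
#' distinguishing metric millimetre coordinates from the normalized
#' \eqn{[-1, 1]} frame used by the registration solvers.
#'
#' @param points numeric matrix, N x 3.
#' @param normals optional numeric matrix, N x 3, rows of unit length.
#' @param frame either `"metric_mm"` or `"normalized"`.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL, frame = c("metric_mm", "normalized")) {
  frame <- match.arg(frame)
  points <- as_coord_matrix(points, "points")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  if (!is.null(normals)) {
    normals <- as_coord_matrix(normals, "normals")
    if (nrow(normals) != nrow(points)) {
      stop("normals count (", nrow(normals), ") must equal point count (", nrow(points), ")")
    }
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6)) stop("normals must have unit norm (1 +/- 1e-6)")
  }
  structure(list(points = points, normals = normals, frame = frame),
            class = "point_cloud")
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(what, " must be an N x 3 matrix")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @exportS3Method base::print
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points, frame=%s, normals=%s>\n",
              nrow(x$points), x$frame, if (is.null(x$normals)) "no" else "yes"))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Triangle mesh container
#'
#' @param vertices numeric matrix, V x 3 (millimetres).
#' @param faces integer matrix, F x 3 of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as_coord_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3) stop("faces must be an F x 3 index matrix")
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("face indices out of range [1, ", nrow(vertices), "]")
    }
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]
    if (any(degen)) stop("degenerate face(s) with repeated vertex at row(s) ",
                         paste(head(which(degen), 5), collapse = ", "))
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @exportS3Method base::print
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation numeric length-3 vector, same units as the clouds it
#'   acts on.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthogonal within 1e-9")
  }
  if (abs(det(rotation) - 1) > 1e-9) stop("rotation must have det +1 (no reflection)")
  translation <- as.numeric(translation)
  if (length(translation) != 3) stop("translation must have length 3")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @exportS3Method base::print
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: angle=%.3f deg, |t|=%.4f>\n",
              rotation_angle(x$rotation), sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Rotation angle of a rotation matrix, in degrees
#' @param R 3 x 3 rotation matrix.
#' @return angle in `[0, 180]` degrees.
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Apply a rigid transform to a point cloud
#'
#' Each point p maps to `R p + t`; normals, when present, are rotated only.
#'
#' @param cloud a `point_cloud` (or bare N x 3 matrix).
#' @param transform a `rigid_transform` in the cloud's units.
#' @return transformed object of the same type.
#' @export
apply_rigid <- function(cloud, transform) {
  if (is.matrix(cloud)) {
    return(sweep(cloud %*% t(transform$rotation), 2, transform$translation, "+"))
  }
  pts <- sweep(cloud$points %*% t(transform$rotation), 2, transform$translation, "+")
  nrm <- if (is.null(cloud$normals)) NULL else cloud$normals %*% t(transform$rotation)
  point_cloud(pts, nrm, cloud$frame)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Compose two rigid transforms
#'
#' `compose_rigid(a, b)` is the transform that applies `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Convert a rigid transform to a 4 x 4 homogeneous matrix (and back)
#' @param transform a `rigid_transform`.
#' @return 4 x 4 numeric matrix.
#' @export
as_homogeneous <- function(transform) {
  H <- diag(4)
  H[1:3, 1:3] <- transform$rotation
  H[1:3, 4] <- transform$translation
  H
}

#' @rdname as_homogeneous
#' @param H 4 x 4 homogeneous matrix with a proper orthogonal upper-left block.
#' @export
from_homogeneous <- function(H) {
  H <- as.matrix(H)
  if (!all(dim(H) == c(4, 4))) stop("expected a 4 x 4 matrix")
  rigid_transform(H[1:3, 1:3], H[1:3, 4])
}

#' Isotropic normalization map between millimetres and the [-1, 1] frame
#'
#' `forward` maps metric to normalized coordinates, `(p - offset) / scale`;
#' `scale` is in millimetres per normalized unit.
#'
#' @param scale positive scalar, mm per normalized unit.
#' @param offset numeric length-3 centering point in mm.
#' @return An object of class `normalization_map`.
#' @export
normalization_map <- function(scale, offset = c(0, 0, 0)) {
  scale <- as.numeric(scale)
  if (length(scale) != 1 || !is.finite(scale) || scale <= 0) stop("scale must be a positive scalar")
  offset <- as.numeric(offset)
  if (length(offset) != 3) stop("offset must have length 3")
  structure(list(scale = scale, offset = offset), class = "normalization_map")
}

#' Normalize a cloud isotropically into [-1, 1]
#'
#' Centers at the axis-aligned bounding-box center and scales by half the
#' largest extent, so the widest axis spans exactly \eqn{[-1, 1]} and all
#' coordinates lie within it. A single isotropic scale preserves rigidity,
#' so a rigid ground-truth transform remains rigid in the normalized frame.
#'
#' @param cloud a `point_cloud` in metric mm.
#' @return list with elements `cloud` (normalized `point_cloud`) and `map`
#'   (the `normalization_map`).
#' @export
normalize_isotropic <- function(cloud) {
  rng <- apply(cloud$points, 2, range)
  extent <- rng[2, ] - rng[1, ]
  if (max(extent) <= 0) stop("degenerate cloud: zero extent on all axes")
  offset <- colMeans(rng)
  scale <- max(extent) / 2
  map <- normalization_map(scale, offset)
  list(cloud = map_to_normalized(cloud, map), map = map)
}

#' Normalize a complete/partial cloud pair with the complete cloud's map
#'
#' Both clouds are transformed by the single min-max map computed from the
#' complete cloud only, mirroring intraoperative practice where only the
#' preoperative (complete) model defines the working frame. Partial points
#' outside the complete cloud's bounding box may exceed \eqn{[-1, 1]};
#' no clipping is applied.
#'
#' @param complete,partial `point_cloud` objects in the same metric frame.
#' @return list with `complete`, `partial` (normalized clouds) and `map`.
#' @export
normalize_with_reference <- function(complete, partial) {
  nz <- normalize_isotropic(complete)
  list(complete = nz$cloud, partial = map_to_normalized(partial, nz$map), map = nz$map)
}

#' Apply or invert a normalization map
#' @param cloud a `point_cloud` or N x 3 matrix.
#' @param map a `normalization_map`.
#' @return the transformed cloud/matrix.
#' @export
map_to_normalized <- function(cloud, map) {
  if (is.matrix(cloud)) return(sweep(cloud, 2, map$offset, "-") / map$scale)
  point_cloud(sweep(cloud$points, 2, map$offset, "-") / map$scale,
              cloud$normals, "normalized")
}

#' @rdname map_to_normalized
#' @export
map_to_metric <- function(cloud, map) {
  if (is.matrix(cloud)) return(sweep(cloud * map$scale, 2, map$offset, "+"))
  point_cloud(sweep(cloud$points * map$scale, 2, map$offset, "+"),
              cloud$normals, "metric_mm")
}

#' Area-weighted surface sampling of a triangle mesh
#'
#' Draws points uniformly by area: faces are selected with probability
#' proportional to their area, then a uniform barycentric coordinate is drawn
#' on each. The default 3500 points balance geometric detail against solver
#' cost for liver-sized organs.
#'
#' @param mesh a `triangle_mesh`.
#' @param n number of points (>= 4).
#' @param seed integer seed; the same seed reproduces the sample exactly.
#' @param with_barycentric if `TRUE`, also return the face index and
#'   barycentric coordinates of every sample so the identical sample can be
#'   carried onto a deformed copy of the mesh.
#' @return a `point_cloud` (metric frame), with attributes `face` and `bary`
#'   when `with_barycentric = TRUE`.
#' @export
sample_surface_points <- function(mesh, n, seed = 0L, with_barycentric = FALSE) {
  if (n < 4) stop("n must be >= 4")
  if (nrow(mesh$faces) < 1) stop("mesh has no faces")
  areas <- face_areas(mesh)
  draw <- withr::with_seed(seed, {
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
    r1 <- runif(n); r2 <- runif(n)
    list(fi = fi, r1 = r1, r2 = r2)
  })
  s <- sqrt(draw$r1)
  bary <- cbind(1 - s, s * (1 - draw$r2), s * draw$r2)
  pts <- barycentric_points(mesh, draw$fi, bary)
  cloud <- point_cloud(pts, frame = "metric_mm")
  if (with_barycentric) {
    attr(cloud, "face") <- draw$fi
    attr(cloud, "bary") <- bary
  }
  cloud
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

barycentric_points <- function(mesh, face_idx, bary) {
  v <- mesh$vertices; f <- mesh$faces[face_idx, , drop = FALSE]
  bary[, 1] * v[f[, 1], , drop = FALSE] +
    bary[, 2] * v[f[, 2], , drop = FALSE] +
    bary[, 3] * v[f[, 3], , drop = FALSE]
}

#' Estimate outward unit normals by local principal-axis fits
#'
#' Fits a plane through each point's k nearest neighbours (PCA); the normal is
#' the smallest principal axis, oriented to point away from the cloud centroid
#' (adequate for convex-ish organ surfaces).
#'
#' @param cloud a `point_cloud`.
#' @param k neighbourhood size (>= 3).
#' @param orient `"outward"` (default) flips normals away from the centroid;
#'   `"none"` leaves the PCA sign.
#' @return the cloud with `normals` filled in.
#' @export
estimate_normals <- function(cloud, k = 20, orient = c("outward", "none")) {
  orient <- match.arg(orient)
  if (k < 3) stop("k must be >= 3")
  pts <- cloud$points
  if (nrow(pts) < k) stop("cloud has fewer than k = ", k, " points")
  nn <- cpp_knn(pts, pts, as.integer(k))
  N <- nrow(pts)
  # per-point neighbourhood covariances assembled in bulk via rowsum
  flat <- as.vector(t(nn$idx))
  grp <- factor(rep(seq_len(N), each = k), levels = seq_len(N))
  nb <- pts[flat, , drop = FALSE]
  mu <- rowsum(nb, grp) / k
  cc <- nb - mu[rep(seq_len(N), each = k), , drop = FALSE]
  prods <- cbind(cc[, 1] * cc[, 1], cc[, 2] * cc[, 2], cc[, 3] * cc[, 3],
                 cc[, 1] * cc[, 2], cc[, 1] * cc[, 3], cc[, 2] * cc[, 3])
  Cv <- rowsum(prods, grp)
  nrm <- matrix(0, N, 3)
  for (i in seq_len(N)) {
    C <- matrix(c(Cv[i, 1], Cv[i, 4], Cv[i, 5],
                  Cv[i, 4], Cv[i, 2], Cv[i, 6],
                  Cv[i, 5], Cv[i, 6], Cv[i, 3]), 3, 3)
    ev <- eigen(C, symmetric = TRUE)
    nrm[i, ] <- ev$vectors[, 3]
  }
  nrm <- nrm / sqrt(rowSums(nrm^2))
  if (orient == "outward") {
    ctr <- colMeans(pts)
    flip <- rowSums(nrm * sweep(pts, 2, ctr)) < 0
    nrm[flip, ] <- -nrm[flip, ]
  }
  point_cloud(pts, nrm, cloud$frame)
}

#' Farthest point sampling (greedy max-min selection)
#'
#' Starting from `start`, repeatedly selects the point maximizing the minimum
#' distance to the already-selected set; ties are broken by the lowest index,
#' so the result is fully deterministic given `start`.
#'
#' @param points N x 3 coordinate matrix (or `point_cloud`).
#' @param n number of points to select (<= N).
#' @param start 1-based index of the first selection.
#' @return integer vector of `n` selected indices, in selection order.
#' @export
farthest_point_sampling <- function(points, n, start = 1L) {
  if (inherits(points, "point_cloud")) points <- points$points
  N <- nrow(points)
  if (n > N) stop("n (", n, ") exceeds point count (", N, ")")
  if (start < 1 || start > N) stop("start index out of range")
  sel <- integer(n)
  sel[1] <- as.integer(start)
  if (n == 1) return(sel)
  mind <- rowSums(sweep(points, 2, points[start, ])^2)
  for (i in 2:n) {
    j <- which.max(mind)  # which.max returns the lowest index on ties
    sel[i] <- j
    d2 <- rowSums(sweep(points, 2, points[j, ])^2)
    mind <- pmin(mind, d2)
  }
  sel
}
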