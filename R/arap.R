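#' Select deformation handles and anchors on a liver lobe
#'
#' Splits the mesh by a plane through the vertex centroid with normal along
#' the widest bounding-box axis (the inter-lobar direction of the phantom).
#' Handles are the vertices of the chosen half lying beyond `margin` of the
#' half-extent from the plane; anchors are the symmetric set in the opposite
#' half. `margin = 0` assigns every off-plane vertex to one of the two sets;
#' larger margins leave a free band that the deformation can bend smoothly.
#'
#' @param mesh a `triangle_mesh`.
#' @param lobe_choice `"left"` or `"right"` (negative / positive side of the
#'   widest axis).
#' @param margin fraction of the half-extent excluded around the split plane.
#' @return list with integer vectors `handles` and `anchors`.
#' @export
select_lobe_handles <- function(mesh, lobe_choice = c("right", "left"), margin = 0.3) {
  lobe_choice <- match.arg(lobe_choice)
  v <- mesh$vertices
  extent <- apply(v, 2, function(x) diff(range(x)))
  ax <- which.max(extent)
  ctr <- mean(v[, ax])
  half <- extent[ax] / 2
  coord <- v[, ax] - ctr
  pos <- which(coord > margin * half)
  neg <- which(coord < -margin * half)
  sel <- if (lobe_choice == "right") list(handles = pos, anchors = neg)
         else list(handles = neg, anchors = pos)
  if (!length(sel$handles) || !length(sel$anchors)) {
    stop("degenerate geometry: empty handle or anchor set at margin ", margin)
  }
  sel
}

#' As-rigid-as-possible mesh deformation
#'
#' Classic local-global ARAP with cotangent weights: anchors are fixed at
#' their rest positions, handles at rest + `displacement`, and the algorithm
#' alternates (a) per-vertex best-fit rotations of one-ring edge sets via a
#' 3x3 orthogonal Procrustes solve and (b) a global sparse Laplacian solve
#' for the free vertices. Negative cotangent weights (obtuse triangles) are
#' clamped to zero so the system stays positive definite and the ARAP energy
#' is non-increasing across iterations.
#'
#' @param mesh a `triangle_mesh`.
#' @param handles,anchors disjoint vertex index sets; handles must be
#'   non-empty, anchors may be empty (e.g. when a rigid motion of the whole
#'   mesh is prescribed through the handles).
#' @param displacement length-3 vector (same units as the mesh) applied to
#'   every handle.
#' @param n_iters number of local-global iterations (>= 1).
#' @return the deformed `triangle_mesh`, with attribute `energy`: the ARAP
#'   energy after each iteration.
#' @export
arap_deform <- function(mesh, handles, anchors, displacement, n_iters = 10L) {
  if (n_iters < 1) stop("n_iters must be >= 1")
  handles <- as.integer(handles); anchors <- as.integer(anchors)
  if (!length(handles)) stop("handles must be non-empty")
  if (length(intersect(handles, anchors))) stop("handles and anchors must be disjoint")
  v <- mesh$vertices
  nv <- nrow(v)
  W <- cotangent_weights(mesh)
  # flat directed-edge arrays (each undirected edge appears in both directions)
  Wt <- as(W, "TsparseMatrix")
  ei <- Wt@i + 1L; ej <- Wt@j + 1L; we <- Wt@x
  E0 <- v[ej, , drop = FALSE] - v[ei, , drop = FALSE]  # rest edges p_j - p_i

  cons <- c(anchors, handles)
  target <- v
  target[handles, ] <- sweep(v[handles, , drop = FALSE], 2, as.numeric(displacement), "+")
  free <- setdiff(seq_len(nv), cons)

  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  if (length(free)) {
    Lff <- L[free, free, drop = FALSE]
    Lfc <- L[free, cons, drop = FALSE]
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Lff), LDL = FALSE),
                   error = function(e) stop("singular Laplacian system (disconnected mesh?): ",
                                            conditionMessage(e)))
  }

  grp <- factor(ei, levels = seq_len(nv))
  p <- target  # current deformed positions (constraints already applied)
  Rflat <- matrix(rep(as.numeric(diag(3)), each = nv), nv, 9)  # column-major R per vertex
  energy <- numeric(n_iters)
  for (it in seq_len(n_iters)) {
    # local step: per-vertex covariance S_i = sum_e w_e e0 e1^T via rowsum,
    # then a 3x3 orthogonal-Procrustes solve per vertex
    E1 <- p[ej, , drop = FALSE] - p[ei, , drop = FALSE]
    Scols <- matrix(0, length(ei), 9)
    for (q in 1:3) for (r in 1:3) {
      Scols[, (r - 1) * 3 + q] <- we * E0[, q] * E1[, r]  # S[q, r], column-major
    }
    Sv <- rowsum(Scols, grp)
    for (i in seq_len(nv)) {
      S <- matrix(Sv[i, ], 3, 3)
      sv <- svd(S)
      R <- sv$v %*% t(sv$u)
      if (det(R) < 0) {
        sv$v[, 3] <- -sv$v[, 3]
        R <- sv$v %*% t(sv$u)
      }
      Rflat[i, ] <- as.numeric(R)
    }
    # global step: b_i = sum_e (w_e/2) (R_i + R_j)(p_i - p_j) for the
    # Laplacian system L p' = b
    if (length(free)) {
      RS <- Rflat[ei, , drop = FALSE] + Rflat[ej, , drop = FALSE]
      b <- matrix(0, length(ei), 3)
      for (r in 1:3) {  # row r of (R_i+R_j) times -e0
        b[, r] <- -(we / 2) * (RS[, r] * E0[, 1] + RS[, r + 3] * E0[, 2] +
                               RS[, r + 6] * E0[, 3])
      }
      bsum <- rowsum(b, grp)
      rhs <- bsum[free, , drop = FALSE] - as.matrix(Lfc %*% target[cons, , drop = FALSE])
      p[free, ] <- as.matrix(Matrix::solve(ch, rhs))
    }
    # ARAP energy with the current rotations
    E1 <- p[ej, , drop = FALSE] - p[ei, , drop = FALSE]
    RE <- Rflat[ei, , drop = FALSE]
    D2 <- 0
    for (r in 1:3) {
      rot <- RE[, r] * E0[, 1] + RE[, r + 3] * E0[, 2] + RE[, r + 6] * E0[, 3]
      D2 <- D2 + (E1[, r] - rot)^2
    }
    energy[it] <- sum(we * D2)
  }
  out <- triangle_mesh(p, mesh$faces)
  attr(out, "energy") <- energy
  out
}

# Symmetric cotangent weight matrix; negative weights clamped to zero.
cotangent_weights <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  cot_at <- function(a, b, cc) {
    # cotangent of the angle at vertex a in triangle (a, b, c)
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    dot <- rowSums(u * w)
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    dot / pmax(sqrt(cx^2 + cy^2 + cz^2), 1e-12)
  }
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  x <- c(cot_at(f[, 3], f[, 1], f[, 2]),
         cot_at(f[, 1], f[, 2], f[, 3]),
         cot_at(f[, 2], f[, 3], f[, 1])) / 2
  x <- pmax(x, 0)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x),
                            dims = rep(nrow(v), 2))
  W
}
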