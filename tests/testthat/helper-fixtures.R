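# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  hit <- get0(name, envir = .fixtures)
  if (!is.null(hit)) return(hit)
  val <- builder()
  assign(name, val, envir = .fixtures)
  val
}

phantom_mesh <- function() fixture("phantom", function() make_liver_phantom(0, 200))

default_pair <- function() {
  fixture("default_pair", function() generate_pair(phantom_mesh(),
                                                   generation_config(), seed = 42))
}

# unit square in the z = 0 plane, two triangles of equal area
unit_square_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

# axis-aligned ellipsoid mesh (stretched icosphere), for bar-like ARAP tests
ellipsoid_mesh <- function(semi = c(3, 1, 1), subdivisions = 2) {
  ico <- liverbench:::icosphere(subdivisions)
  triangle_mesh(sweep(ico$vertices, 2, semi, "*"), ico$faces)
}

random_rotation <- function() {
  ax <- rnorm(3)
  axis_angle_matrix(ax / sqrt(sum(ax^2)), runif(1, 0, 180))
}

random_rigid <- function(t_scale = 1) {
  rigid_transform(random_rotation(), runif(3, -t_scale, t_scale))
}

# independent greedy max-min oracle (explicit loops, no shared code path)
fps_bruteforce <- function(points, n, start) {
  sel <- start
  while (length(sel) < n) {
    best_i <- NA
    best_d <- -1
    for (i in seq_len(nrow(points))) {
      if (i %in% sel) next
      di <- min(vapply(sel, function(s) sum((points[i, ] - points[s, ])^2), 0))
      if (di > best_d + 1e-15) {
        best_d <- di
        best_i <- i
      }
    }
    sel <- c(sel, best_i)
  }
  sel
}

# classic (unweighted) Umeyama solve, written independently of the package
umeyama_oracle <- function(src, tgt) {
  cs <- colMeans(src); ct <- colMeans(tgt)
  H <- t(sweep(src, 2, cs)) %*% sweep(tgt, 2, ct)
  sv <- svd(H)
  S <- diag(3)
  if (det(sv$v %*% t(sv$u)) < 0) S[3, 3] <- -1
  R <- sv$v %*% S %*% t(sv$u)
  list(R = R, t = ct - as.numeric(R %*% cs))
}

transform_close <- function(pred, gt, tol_deg, tol_units) {
  ang <- rotation_angle(pred$rotation %*% t(gt$rotation))
  dt <- sqrt(sum((pred$translation - gt$translation)^2))
  ang <= tol_deg && dt <= tol_units
}
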