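#' Procedural two-lobed liver phantom
#'
#' Builds a watertight, genus-0 triangle mesh emulating the gross shape of an
#' adult human liver: two overlapping smoothed ellipsoids (the larger right
#' lobe and smaller left lobe) blended by a soft implicit-surface union and
#' extracted by radial ray-casting onto a subdivided icosahedron. The widest
#' bounding-box extent is scaled to `width` (an adult liver measures roughly
#' 20 cm across). A seeded jitter of lobe centres, semi-axes and a smooth
#' low-frequency surface bump provides per-subject anatomical variation.
#'
#' @param seed integer seed controlling the shape jitter; the same seed
#'   returns an identical mesh.
#' @param width target widest extent in mm (default 200).
#' @param subdivisions icosphere subdivision level (4 gives 2562 vertices /
#'   5120 faces, enough for surface sampling and fast deformation).
#' @return a `triangle_mesh` in metric mm.
#' @export
make_liver_phantom <- function(seed = 0L, width = 200, subdivisions = 4L) {
  if (width <= 0) stop("width must be positive")
  ico <- icosphere(subdivisions)
  shape <- withr::with_seed(seed, {
    list(
      c1 = c(-0.35, 0, 0) + runif(3, -0.05, 0.05),
      a1 = c(0.65, 0.45, 0.35) * runif(3, 0.92, 1.08),
      c2 = c(0.45, 0.02, 0.05) + runif(3, -0.05, 0.05),
      a2 = c(0.50, 0.36, 0.30) * runif(3, 0.92, 1.08),
      bump_amp = runif(1, 0.02, 0.05),
      bump_w1 = rnorm(3), bump_w2 = rnorm(3), bump_phase = runif(1, 0, 2 * pi)
    )
  })
  field <- function(p) {
    q1 <- rowSums(sweep(sweep(p, 2, shape$c1), 2, shape$a1, "/")^2)
    q2 <- rowSums(sweep(sweep(p, 2, shape$c2), 2, shape$a2, "/")^2)
    k <- 8
    soft <- -log(exp(-k * (q1 - 1)) + exp(-k * (q2 - 1))) / k
    u <- p / pmax(sqrt(rowSums(p^2)), 1e-12)
    bump <- shape$bump_amp * sin(3 * (u %*% shape$bump_w1) + shape$bump_phase) *
      cos(3 * (u %*% shape$bump_w2))
    soft + as.vector(bump)
  }
  dirs <- ico$vertices
  lo <- rep(0.05, nrow(dirs)); hi <- rep(3.0, nrow(dirs))
  for (it in 1:52) {
    mid <- (lo + hi) / 2
    inside <- field(dirs * mid) < 0
    lo[inside] <- mid[inside]
    hi[!inside] <- mid[!inside]
  }
  verts <- dirs * ((lo + hi) / 2)
  extent <- apply(verts, 2, function(v) diff(range(v)))
  verts <- verts * (width / max(extent))
  triangle_mesh(verts, ico$faces)
}

# Subdivided icosahedron with unit-sphere vertices; vertex count 10*4^n + 2.
icosphere <- function(subdivisions = 4L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    cache <- new.env(parent = emptyenv())
    verts <- v
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      hit <- get0(key, envir = cache)
      if (!is.null(hit)) return(hit)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      assign(key, idx, envir = cache)
      idx
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts; f <- nf
  }
  list(vertices = v, faces = f)
}

#' Euler characteristic of a triangle mesh
#'
#' `V - E + F`; equals 2 for a closed genus-0 surface.
#' @param mesh a `triangle_mesh`.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  ne <- nrow(unique(edges))
  nrow(mesh$vertices) - ne + nrow(f)
}
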