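#' Load a triangle mesh from PLY or OBJ
#'
#' PLY in ASCII or binary little-endian form; OBJ read-only (positions and
#' triangular faces, 1-based indices, `v/vt/vn` face syntax accepted).
#' Vertex order is preserved from the file; degenerate faces (repeated vertex)
#' and vertices referenced by no face are dropped.
#'
#' @param path path to a `.ply` or `.obj` file.
#' @return a `triangle_mesh`.
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    ply = read_ply_raw(path),
    obj = read_obj_raw(path),
    stop("unsupported mesh format '.", ext, "' (PLY or OBJ expected)"))
  if (is.null(parsed$faces) || nrow(parsed$faces) == 0) {
    stop("mesh file has no faces: ", path)
  }
  clean_mesh(parsed$vertices, parsed$faces)
}

clean_mesh <- function(vertices, faces) {
  degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]
  faces <- faces[!degen, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  if (length(used) < nrow(vertices)) {
    remap <- integer(nrow(vertices))
    remap[used] <- seq_along(used)
    vertices <- vertices[used, , drop = FALSE]
    faces <- matrix(remap[faces], ncol = 3)
  }
  triangle_mesh(vertices, faces)
}

#' Save a triangle mesh as PLY
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param binary write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, binary = TRUE) {
  write_ply_impl(path, mesh$vertices, normals = NULL, faces = mesh$faces, binary = binary)
  invisible(path)
}

#' Read / write point clouds as PLY
#'
#' Cloud PLY files carry `x,y,z` and, optionally, `nx,ny,nz` properties.
#'
#' @param path path to a `.ply` file.
#' @param frame frame tag to attach to the loaded cloud.
#' @return a `point_cloud`.
#' @export
read_cloud <- function(path, frame = c("metric_mm", "normalized")) {
  frame <- match.arg(frame)
  parsed <- read_ply_raw(path)
  point_cloud(parsed$vertices, parsed$normals, frame)
}

#' @rdname read_cloud
#' @param cloud a `point_cloud`.
#' @param binary write binary little-endian (default) or ASCII.
#' @export
write_cloud <- function(cloud, path, binary = TRUE) {
  write_ply_impl(path, cloud$points, normals = cloud$normals, faces = NULL, binary = binary)
  invisible(path)
}

# ---- PLY ----

read_ply_raw <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  marker <- grepRaw("end_header\r\n", raw, fixed = TRUE)
  marker_len <- 12L
  if (!length(marker)) {
    marker <- grepRaw("end_header\n", raw, fixed = TRUE)
    marker_len <- 11L
  }
  if (!length(marker)) stop("invalid PLY (no end_header): ", path)
  body_off <- marker[1] + marker_len
  header <- strsplit(rawToChar(raw[seq_len(marker[1] - 1)]), "\r?\n")[[1]]
  header <- trimws(header)
  if (!identical(header[1], "ply")) stop("invalid PLY (missing 'ply' magic): ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop("invalid PLY (format line): ", path)
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format '", fmt, "'")
  }
  # parse element/property declarations in order
  elements <- list(); cur <- NULL
  for (ln in header[-1]) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <- list(name = tok[5], list = TRUE,
                                                   count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <- list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop("invalid PLY (no vertex element): ", path)

  if (fmt == "ascii") {
    body <- strsplit(rawToChar(raw[body_off:length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    parse_ply_ascii(elements, body, path)
  } else {
    parse_ply_binary(elements, raw, body_off, path)
  }
}

ply_type_size <- function(type) {
  switch(type,
    char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
    double = 8L, float64 = 8L,
    stop("unsupported PLY property type '", type, "'"))
}

ply_read_scalar <- function(raw, off, type) {
  sz <- ply_type_size(type)
  bytes <- raw[off:(off + sz - 1)]
  val <- switch(type,
    char = , int8 = readBin(bytes, "integer", size = 1, signed = TRUE),
    uchar = , uint8 = readBin(bytes, "integer", size = 1, signed = FALSE),
    short = , int16 = readBin(bytes, "integer", size = 2, signed = TRUE, endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", size = 2, signed = FALSE, endian = "little"),
    int = , int32 = , uint = , uint32 = readBin(bytes, "integer", size = 4, endian = "little"),
    float = , float32 = readBin(bytes, "double", size = 4, endian = "little"),
    double = , float64 = readBin(bytes, "double", size = 8, endian = "little"))
  list(value = as.numeric(val), next_off = off + sz)
}

extract_vertex_block <- function(mat, names) {
  need <- c("x", "y", "z")
  if (!all(need %in% names)) stop("PLY vertex element lacks x/y/z properties")
  vertices <- mat[, match(need, names), drop = FALSE]
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% names)) {
    normals <- mat[, match(c("nx", "ny", "nz"), names), drop = FALSE]
  }
  list(vertices = vertices, normals = normals)
}

parse_ply_ascii <- function(elements, body, path) {
  pos <- 1L
  vertices <- NULL; normals <- NULL; faces <- NULL
  for (el in elements) {
    if (el$count == 0) next
    lines <- body[pos:(pos + el$count - 1)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      pn <- vapply(el$props, function(p) p$name, "")
      mat <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))),
                    nrow = el$count, byrow = TRUE)
      if (ncol(mat) != length(pn)) stop("malformed PLY vertex row in ", path)
      blk <- extract_vertex_block(mat, pn)
      vertices <- blk$vertices; normals <- blk$normals
    } else if (el$name == "face") {
      rows <- lapply(strsplit(trimws(lines), "\\s+"), as.integer)
      bad <- which(vapply(rows, function(r) r[1] != 3L, TRUE))
      if (length(bad)) stop("non-triangular face at row ", bad[1], " in ", path)
      faces <- do.call(rbind, lapply(rows, function(r) r[2:4])) + 1L
    }
  }
  list(vertices = vertices, normals = normals, faces = faces)
}

parse_ply_binary <- function(elements, raw, off, path) {
  vertices <- NULL; normals <- NULL; faces <- NULL
  for (el in elements) {
    if (el$count == 0) next
    if (el$name == "vertex" && !any(vapply(el$props, function(p) p$list, TRUE))) {
      types <- vapply(el$props, function(p) p$type, "")
      sizes <- vapply(types, ply_type_size, 1L)
      stride <- sum(sizes)
      if (length(unique(types)) == 1 && types[1] %in% c("float", "float32", "double", "float64")) {
        sz <- sizes[1]
        vals <- readBin(raw[off:(off + el$count * stride - 1)], "double",
                        n = el$count * length(types), size = sz, endian = "little")
        mat <- matrix(vals, nrow = el$count, byrow = TRUE)
      } else {
        mat <- matrix(0, el$count, length(types))
        o <- off
        for (i in seq_len(el$count)) for (j in seq_along(types)) {
          r <- ply_read_scalar(raw, o, types[j]); mat[i, j] <- r$value; o <- r$next_off
        }
      }
      off <- off + el$count * stride
      blk <- extract_vertex_block(mat, vapply(el$props, function(p) p$name, ""))
      vertices <- blk$vertices; normals <- blk$normals
    } else if (el$name == "face") {
      lp <- el$props[[1]]
      faces <- matrix(0L, el$count, 3)
      for (i in seq_len(el$count)) {
        r <- ply_read_scalar(raw, off, lp$count_type)
        if (r$value != 3) stop("non-triangular face at row ", i, " in ", path)
        off <- r$next_off
        for (j in 1:3) {
          r <- ply_read_scalar(raw, off, lp$type)
          faces[i, j] <- as.integer(r$value) + 1L
          off <- r$next_off
        }
      }
    } else {
      stop("unsupported PLY element '", el$name, "' in ", path)
    }
  }
  list(vertices = vertices, normals = normals, faces = faces)
}

write_ply_impl <- function(path, vertices, normals = NULL, faces = NULL, binary = TRUE) {
  nv <- nrow(vertices)
  props <- c("x", "y", "z")
  mat <- vertices
  if (!is.null(normals)) {
    props <- c(props, "nx", "ny", "nz")
    mat <- cbind(vertices, normals)
  }
  header <- c("ply",
              sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
              sprintf("element vertex %d", nv),
              sprintf("property double %s", props))
  if (!is.null(faces)) {
    header <- c(header,
                sprintf("element face %d", nrow(faces)),
                "property list uchar int vertex_indices")
  }
  header <- c(header, "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    writeBin(as.vector(t(mat)), con, size = 8, endian = "little")
    if (!is.null(faces)) {
      f0 <- faces - 1L
      for (i in seq_len(nrow(faces))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
      }
    }
  } else {
    writeLines(apply(mat, 1, function(r) paste(format(r, digits = 17, trim = TRUE),
                                               collapse = " ")), con)
    if (!is.null(faces)) {
      f0 <- faces - 1L
      writeLines(apply(f0, 1, function(r) paste(c(3L, r), collapse = " ")), con)
    }
  }
  invisible(path)
}

# ---- OBJ ----

read_obj_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (!length(vlines)) stop("OBJ file has no vertices: ", path)
  vertices <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  }))
  faces <- NULL
  if (length(flines)) {
    rows <- lapply(strsplit(trimws(flines), "\\s+"), function(tok) {
      idx <- vapply(tok[-1], function(t) as.integer(strsplit(t, "/")[[1]][1]), 1L)
      if (length(idx) != 3) stop("non-triangular OBJ face: '", paste(tok, collapse = " "), "'")
      if (any(is.na(idx)) || any(idx == 0)) stop("invalid OBJ face index in '",
                                                 paste(tok, collapse = " "), "'")
      idx[idx < 0] <- nrow(vertices) + 1L + idx[idx < 0]
      idx
    })
    faces <- do.call(rbind, rows)
  }
  list(vertices = vertices, normals = NULL, faces = faces)
}

# ---- rigid transform JSON ----

#' Serialize a rigid transform to / from JSON
#'
#' The on-disk form is a 4 x 4 row-major homogeneous matrix.
#'
#' @param transform a `rigid_transform`.
#' @param path output (input) path.
#' @return `path` (`rigid_transform`), invisibly for the writer.
#' @export
write_transform_json <- function(transform, path) {
  H <- as_homogeneous(transform)
  jsonlite::write_json(list(matrix = apply(H, 1, identity, simplify = FALSE)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- as.matrix(obj$matrix)  # rows were written in order
  if (!all(dim(H) == c(4, 4))) H <- do.call(rbind, obj$matrix)
  from_homogeneous(H)
}
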