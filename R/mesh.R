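#' Triangle mesh container
#'
#' A minimal closed triangulated surface: an `n x 3` matrix of vertex
#' coordinates in millimetres and an `m x 3` integer matrix of 1-based
#' vertex indices with counter-clockwise winding seen from outside.
#'
#' @param vertices Numeric matrix, `n x 3`, columns x/y/z in mm.
#' @param faces Integer matrix, `m x 3`, 1-based vertex indices.
#' @return An object of class `oza_mesh`.
#' @export
oza_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  structure(list(vertices = vertices, faces = faces), class = "oza_mesh")
}

#' @export
print.oza_mesh <- function(x, ...) {
  cat(sprintf(
    "<oza_mesh> %d vertices, %d faces, Euler characteristic %d\n",
    nrow(x$vertices), nrow(x$faces), euler_characteristic(x)
  ))
  invisible(x)
}

# Undirected edge table, one row per directed half-edge.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Euler characteristic V - E + F of a mesh
#'
#' Equals 2 for a closed genus-0 surface.
#'
#' @param mesh An [oza_mesh()].
#' @return Integer.
#' @export
euler_characteristic <- function(mesh) {
  e <- mesh_edges(mesh)
  n_edges <- nrow(unique(e))
  nrow(mesh$vertices) - n_edges + nrow(mesh$faces)
}

#' Test whether a mesh is watertight
#'
#' Every undirected edge must be shared by exactly two faces, traversed in
#' opposite directions (consistent orientation).
#'
#' @param mesh An [oza_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

# Per-face un-normalised outward normals and triangle areas.
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
}

#' Signed volume enclosed by a mesh
#'
#' Positive when face winding is outward (divergence theorem over the
#' triangle fan from the origin).
#'
#' @param mesh An [oza_mesh()].
#' @return Volume in mm^3, signed.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(
    a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
    a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  ) / 6
}

# Icosahedron with unit circumradius, outward CCW winding.
icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1)
  )
  v <- v / sqrt(1 + p^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  oza_mesh(v, f)
}

# One 4-to-1 subdivision with midpoint reprojection onto the unit sphere.
subdivide_sphere <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  ue <- e[!duplicated(key), , drop = FALSE]
  mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  midx <- stats::setNames(nrow(v) + seq_len(nrow(ue)), paste(ue[, 1], ue[, 2]))
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m12 <- midx[ekey(f[, 1], f[, 2])]
  m23 <- midx[ekey(f[, 2], f[, 3])]
  m31 <- midx[ekey(f[, 3], f[, 1])]
  newf <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  oza_mesh(rbind(v, mid), newf)
}

#' Unit icosphere mesh
#'
#' @param subdivisions Number of 4-to-1 refinement rounds (>= 0).
#' @return An [oza_mesh()] approximating the unit sphere.
#' @export
icosphere <- function(subdivisions = 4) {
  stopifnot(subdivisions >= 0)
  m <- icosahedron()
  for (i in seq_len(subdivisions)) m <- subdivide_sphere(m)
  m
}

#' Triangulated ellipsoid mesh
#'
#' An icosphere scaled anisotropically by the semi-axes and translated to
#' `center`. Winding stays outward under positive scaling.
#'
#' @param semi_axes Length-3 positive numeric, semi-axes in mm (x, y, z).
#' @param center Length-3 numeric, centre in mm.
#' @param subdivisions Icosphere refinement rounds (>= 3 recommended for
#'   sub-millimetre surface fidelity at cranial scale).
#' @return An [oza_mesh()].
#' @export
ellipsoid_mesh <- function(semi_axes, center = c(0, 0, 0), subdivisions = 4) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3 || any(!is.finite(semi_axes)) || any(semi_axes <= 0)) {
    stop("semi_axes must be three positive numbers (mm)", call. = FALSE)
  }
  m <- icosphere(subdivisions)
  v <- sweep(m$vertices, 2, semi_axes, `*`)
  v <- sweep(v, 2, as.numeric(center), `+`)
  oza_mesh(v, m$faces)
}

#' Write a mesh to PLY, STL or OBJ
#'
#' ASCII variants of the three formats; the format is inferred from the
#' file extension unless given.
#'
#' @param mesh An [oza_mesh()].
#' @param path Output file path.
#' @param format One of `"ply"`, `"stl"`, `"obj"`; default from extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "stl", "obj"))
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "ply") {
    writeLines(c(
      "ply", "format ascii 1.0", "comment units mm",
      sprintf("element vertex %d", nrow(v)),
      "property double x", "property double y", "property double z",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices", "end_header"
    ), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (format == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    n <- face_normals(mesh)
    n <- n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
    writeLines("solid oza_mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "  outer loop",
        sprintf("    vertex %.9g %.9g %.9g",
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "  endloop", "endfacet"
      ), con)
    }
    writeLines("endsolid oza_mesh", con)
  }
  invisible(path)
}

#' Read a mesh from PLY, STL or OBJ
#'
#' Supports the ASCII variants written by [write_mesh()] (and plain
#' third-party ASCII files of the same formats).
#'
#' @param path Input file path.
#' @param format One of `"ply"`, `"stl"`, `"obj"`; default from extension.
#' @return An [oza_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "stl", "obj"))
  lines <- readLines(path)
  if (format == "ply") {
    if (!grepl("ascii", lines[2])) stop("only ASCII PLY is supported", call. = FALSE)
    nv <- as.integer(sub(".*element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub(".*element face ", "", grep("^element face", lines, value = TRUE)[1]))
    body <- which(lines == "end_header") + 1L
    v <- do.call(rbind, lapply(strsplit(lines[body:(body + nv - 1L)], "\\s+"),
                               function(x) as.numeric(x[1:3])))
    fr <- lines[(body + nv):(body + nv + nf - 1L)]
    f <- do.call(rbind, lapply(strsplit(fr, "\\s+"),
                               function(x) as.integer(x[2:4]) + 1L))
    oza_mesh(v, f)
  } else if (format == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"),
                               function(x) as.integer(sub("/.*", "", x[2:4]))))
    oza_mesh(v, f)
  } else {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    vv <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                function(x) as.numeric(x[2:4])))
    # merge duplicated corner vertices back into shared indices
    key <- apply(round(vv, 9), 1, paste, collapse = ",")
    uid <- match(key, unique(key))
    v <- vv[!duplicated(key), , drop = FALSE]
    f <- matrix(uid, ncol = 3, byrow = TRUE)
    oza_mesh(v, f)
  }
}
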