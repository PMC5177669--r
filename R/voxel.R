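#' Voxelize a cranial mesh and re-extract its surface
#'
#' Optional CT-phantom path: rasterises the closed mesh into a binary
#' occupancy volume (column-parity fill along z) and re-extracts a
#' triangulated surface from the voxel boundary. The extracted surface
#' deviates from the source by at most about half a voxel diagonal, so
#' the sampled Hausdorff distance stays within `2 * voxel_mm`.
#'
#' @param x An [oza_mesh()] or an `anatomy_model`.
#' @param voxel_mm Isotropic voxel spacing, mm, in `[0.25, 2]`.
#' @param margin_voxels Padding around the mesh bounding box.
#' @return A list of class `voxel_phantom`: `volume` (3-D 0/1 integer
#'   array), `origin` (mm position of the grid corner), `voxel_mm`, and
#'   `mesh` (the extracted [oza_mesh()]).
#' @export
voxelize_and_extract <- function(x, voxel_mm = 1.0, margin_voxels = 2L) {
  if (inherits(x, "anatomy_model")) x <- x$mesh
  stopifnot(inherits(x, "oza_mesh"))
  if (!is.finite(voxel_mm) || voxel_mm < 0.25 || voxel_mm > 2.0) {
    stop("voxel_mm must lie in [0.25, 2.0]", call. = FALSE)
  }
  vol <- voxelize_mesh(x, voxel_mm, margin_voxels)
  mesh <- voxel_isosurface(vol$volume, vol$origin, vol$voxel_mm)
  structure(c(vol, list(mesh = mesh)), class = "voxel_phantom")
}

# Column-parity solid voxelization: each (x, y) voxel-column's ray is
# intersected with the mesh in the xy projection (matrix products over
# faces), and voxels between successive crossing pairs are filled.
voxelize_mesh <- function(mesh, voxel_mm, margin_voxels = 2L) {
  v <- mesh$vertices
  f <- mesh$faces
  h <- voxel_mm
  lo <- apply(v, 2, min) - margin_voxels * h
  hi <- apply(v, 2, max) + margin_voxels * h
  dims <- pmax(ceiling((hi - lo) / h), 1L)
  x1 <- v[f[, 1], 1]; y1 <- v[f[, 1], 2]; z1 <- v[f[, 1], 3]
  x2 <- v[f[, 2], 1]; y2 <- v[f[, 2], 2]; z2 <- v[f[, 2], 3]
  x3 <- v[f[, 3], 1]; y3 <- v[f[, 3], 2]; z3 <- v[f[, 3], 3]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  keep <- abs(det) > 1e-12
  cw1 <- rbind((y2 - y3) / det, (x3 - x2) / det,
               -((y2 - y3) * x3 + (x3 - x2) * y3) / det)[, keep, drop = FALSE]
  cw2 <- rbind((y3 - y1) / det, (x1 - x3) / det,
               -((y3 - y1) * x3 + (x1 - x3) * y3) / det)[, keep, drop = FALSE]
  zc <- rbind(z1, z2, z3)[, keep, drop = FALSE]
  xs <- lo[1] + (seq_len(dims[1]) - 0.5) * h + 1.234567e-7
  ys <- lo[2] + (seq_len(dims[2]) - 0.5) * h + 2.345678e-7
  cols <- cbind(rep(xs, times = dims[2]), rep(ys, each = dims[1]), 1)
  vol <- array(0L, dim = dims)
  nface <- ncol(cw1)
  chunk <- max(64L, floor(4e6 / nface))
  ncols <- nrow(cols)
  for (start in seq(1L, ncols, by = chunk)) {
    idx <- start:min(start + chunk - 1L, ncols)
    P <- cols[idx, , drop = FALSE]
    w1 <- P %*% cw1
    w2 <- P %*% cw2
    w3 <- 1 - w1 - w2
    zhit <- w1 * matrix(zc[1, ], nrow(P), nface, byrow = TRUE) +
            w2 * matrix(zc[2, ], nrow(P), nface, byrow = TRUE) +
            w3 * matrix(zc[3, ], nrow(P), nface, byrow = TRUE)
    ins <- (w1 >= 0) & (w2 >= 0) & (w3 >= 0)
    hits <- which(ins, arr.ind = TRUE)
    if (nrow(hits) == 0) next
    zs <- zhit[hits]
    by_col <- split(zs, hits[, 1])
    for (nm in names(by_col)) {
      z <- sort(by_col[[nm]])
      if (length(z) %% 2 != 0) next    # grazing column; skip conservatively
      ci <- idx[as.integer(nm)]
      ix <- ((ci - 1L) %% dims[1]) + 1L
      iy <- ((ci - 1L) %/% dims[1]) + 1L
      for (p in seq(1L, length(z), by = 2L)) {
        k1 <- ceiling((z[p] - lo[3]) / h + 0.5)
        k2 <- floor((z[p + 1] - lo[3]) / h + 0.5)
        if (k2 >= k1) {
          k1 <- max(k1, 1L); k2 <- min(k2, dims[3])
          vol[ix, iy, k1:k2] <- 1L
        }
      }
    }
  }
  list(volume = vol, origin = lo, voxel_mm = h)
}

#' Extract the boundary surface of a binary volume
#'
#' Cuberille extraction: every voxel face separating an occupied voxel
#' from an empty one becomes two triangles on the voxel lattice, with
#' outward-consistent winding and shared (deduplicated) corner vertices.
#'
#' @param volume 3-D 0/1 array.
#' @param origin Length-3 numeric, mm position of the grid corner.
#' @param voxel_mm Voxel spacing, mm.
#' @return An [oza_mesh()].
#' @export
voxel_isosurface <- function(volume, origin = c(0, 0, 0), voxel_mm = 1.0) {
  if (sum(volume) == 0) {
    stop("cannot extract a surface: the volume is empty (all background)",
         call. = FALSE)
  }
  d <- dim(volume)
  occ <- array(FALSE, d + 2L)
  occ[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- volume > 0
  W <- d[1] + 1L; H <- d[2] + 1L   # corner-node lattice extents
  node_id <- function(i, j, k) 1 + i + W * (j + H * k)
  quads_i <- list(); quads_j <- list(); quads_k <- list(); quads_dir <- list()
  q <- 0L
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_along(shifts)) {
    sh <- shifts[[s]]
    nb <- occ[(2:(d[1] + 1)) + sh[1], (2:(d[2] + 1)) + sh[2],
              (2:(d[3] + 1)) + sh[3], drop = FALSE]
    bnd <- which((volume > 0) & !nb, arr.ind = TRUE)
    if (nrow(bnd) == 0) next
    q <- q + 1L
    quads_i[[q]] <- bnd[, 1]; quads_j[[q]] <- bnd[, 2]; quads_k[[q]] <- bnd[, 3]
    quads_dir[[q]] <- rep.int(s, nrow(bnd))
  }
  i <- unlist(quads_i); j <- unlist(quads_j); k <- unlist(quads_k)
  dir <- unlist(quads_dir)
  # voxel (i,j,k) spans nodes (i-1..i, j-1..j, k-1..k); build the 4 corner
  # nodes of each boundary face with outward winding
  corner <- function(ci, cj, ck) node_id(ci, cj, ck)
  n_faces <- length(i)
  c1 <- c2 <- c3 <- c4 <- integer(n_faces)
  for (s in 1:6) {
    m <- dir == s
    if (!any(m)) next
    ii <- i[m]; jj <- j[m]; kk <- k[m]
    if (s == 1) {        # +x face at node plane x = i
      c1[m] <- corner(ii, jj - 1L, kk - 1L); c2[m] <- corner(ii, jj, kk - 1L)
      c3[m] <- corner(ii, jj, kk);           c4[m] <- corner(ii, jj - 1L, kk)
    } else if (s == 2) { # -x face at x = i-1
      c1[m] <- corner(ii - 1L, jj - 1L, kk - 1L); c2[m] <- corner(ii - 1L, jj - 1L, kk)
      c3[m] <- corner(ii - 1L, jj, kk);           c4[m] <- corner(ii - 1L, jj, kk - 1L)
    } else if (s == 3) { # +y
      c1[m] <- corner(ii - 1L, jj, kk - 1L); c2[m] <- corner(ii - 1L, jj, kk)
      c3[m] <- corner(ii, jj, kk);           c4[m] <- corner(ii, jj, kk - 1L)
    } else if (s == 4) { # -y
      c1[m] <- corner(ii - 1L, jj - 1L, kk - 1L); c2[m] <- corner(ii, jj - 1L, kk - 1L)
      c3[m] <- corner(ii, jj - 1L, kk);           c4[m] <- corner(ii - 1L, jj - 1L, kk)
    } else if (s == 5) { # +z
      c1[m] <- corner(ii - 1L, jj - 1L, kk); c2[m] <- corner(ii, jj - 1L, kk)
      c3[m] <- corner(ii, jj, kk);           c4[m] <- corner(ii - 1L, jj, kk)
    } else {             # -z
      c1[m] <- corner(ii - 1L, jj - 1L, kk - 1L); c2[m] <- corner(ii - 1L, jj, kk - 1L)
      c3[m] <- corner(ii, jj, kk - 1L);           c4[m] <- corner(ii, jj - 1L, kk - 1L)
    }
  }
  nodes <- unique(c(c1, c2, c3, c4))
  t0 <- nodes - 1
  ni <- t0 %% W
  nj <- (t0 %/% W) %% H
  nk <- t0 %/% (W * H)
  verts <- cbind(origin[1] + ni * voxel_mm,
                 origin[2] + nj * voxel_mm,
                 origin[3] + nk * voxel_mm)
  faces <- rbind(cbind(match(c1, nodes), match(c2, nodes), match(c3, nodes)),
                 cbind(match(c1, nodes), match(c3, nodes), match(c4, nodes)))
  oza_mesh(verts, faces)
}

#' Write a voxel phantom volume as NIfTI-1
#'
#' Requires the optional RNifti package; records the voxel spacing in the
#' header so the phantom can be loaded in standard imaging tools.
#'
#' @param phantom A [voxelize_and_extract()] result.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_phantom_nifti <- function(phantom, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI export requires the RNifti package", call. = FALSE)
  }
  img <- RNifti::asNifti(phantom$volume * 1L,
                         pixdim = rep(phantom$voxel_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
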