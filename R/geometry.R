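#' Ray-mesh intersections (Moller-Trumbore)
#'
#' Intersects the ray `origin + t * direction` (t in mm for a unit
#' direction) with every triangle of a mesh and returns all forward hits.
#' Grazing configurations (a hit within `eps` of a triangle edge) are
#' resolved deterministically by nudging the origin `1e-6` mm along the
#' ray and re-casting.
#'
#' @param origin Length-3 numeric, ray origin in mm.
#' @param direction Length-3 numeric; normalised internally so `t` is mm.
#' @param mesh An [oza_mesh()].
#' @param eps Barycentric tolerance classifying a hit as grazing.
#' @return A tibble with columns `t` (mm, ascending) and `face` (index).
#' @export
ray_mesh_intersections <- function(origin, direction, mesh, eps = 1e-12) {
  origin <- as.numeric(origin)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-9) {
    stop("ray direction is undefined (zero length)", call. = FALSE)
  }
  d <- as.numeric(direction) / nrm
  cast <- function(o) {
    v <- mesh$vertices
    f <- mesh$faces
    v0 <- v[f[, 1], , drop = FALSE]
    e1 <- v[f[, 2], , drop = FALSE] - v0
    e2 <- v[f[, 3], , drop = FALSE] - v0
    h1 <- d[2] * e2[, 3] - d[3] * e2[, 2]
    h2 <- d[3] * e2[, 1] - d[1] * e2[, 3]
    h3 <- d[1] * e2[, 2] - d[2] * e2[, 1]
    a <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
    ok <- abs(a) > 1e-14
    fi <- 1 / a
    s1 <- o[1] - v0[, 1]; s2 <- o[2] - v0[, 2]; s3 <- o[3] - v0[, 3]
    u <- fi * (s1 * h1 + s2 * h2 + s3 * h3)
    q1 <- s2 * e1[, 3] - s3 * e1[, 2]
    q2 <- s3 * e1[, 1] - s1 * e1[, 3]
    q3 <- s1 * e1[, 2] - s2 * e1[, 1]
    vb <- fi * (d[1] * q1 + d[2] * q2 + d[3] * q3)
    t <- fi * (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3)
    hit <- ok & u >= -eps & vb >= -eps & (u + vb) <= 1 + eps & t > 1e-9
    grazing <- any(hit & (u < eps | vb < eps | u + vb > 1 - eps))
    list(t = t[hit], face = which(hit), grazing = grazing)
  }
  res <- cast(origin)
  if (res$grazing) {
    res2 <- cast(origin + 1e-6 * d)
    res <- list(t = res2$t + 1e-6, face = res2$face, grazing = FALSE)
  }
  ord <- order(res$t)
  tibble::tibble(t = res$t[ord], face = res$face[ord])
}

#' Point-in-mesh test by ray-casting parity
#'
#' Casts a vertical (+z) ray from each point and counts crossings with the
#' closed surface; odd parity means inside. Triangles are intersected in
#' the xy projection, which makes the whole batch a handful of matrix
#' products. Points are deterministically nudged off triangle edges.
#'
#' @param points Numeric matrix `n x 3` (or length-3 vector), mm.
#' @param mesh A watertight [oza_mesh()].
#' @param chunk Points per block (memory/speed trade-off).
#' @return Logical vector of length `n`.
#' @export
points_in_mesh <- function(points, mesh, chunk = 512L) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  v <- mesh$vertices
  f <- mesh$faces
  x1 <- v[f[, 1], 1]; y1 <- v[f[, 1], 2]; z1 <- v[f[, 1], 3]
  x2 <- v[f[, 2], 1]; y2 <- v[f[, 2], 2]; z2 <- v[f[, 2], 3]
  x3 <- v[f[, 3], 1]; y3 <- v[f[, 3], 2]; z3 <- v[f[, 3], 3]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  keep <- abs(det) > 1e-12          # drop xy-degenerate (vertical) triangles
  # barycentric coords w1, w2 are affine in (x, y): [x y 1] %*% coef
  cw1 <- rbind((y2 - y3) / det, (x3 - x2) / det,
               -((y2 - y3) * x3 + (x3 - x2) * y3) / det)[, keep, drop = FALSE]
  cw2 <- rbind((y3 - y1) / det, (x1 - x3) / det,
               -((y3 - y1) * x3 + (x1 - x3) * y3) / det)[, keep, drop = FALSE]
  zc <- rbind(z1, z2, z3)[, keep, drop = FALSE]
  n <- nrow(points)
  inside <- logical(n)
  # deterministic sub-nanometre nudge avoids edge/vertex double counting
  jit <- c(1.234567e-7, 2.345678e-7)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    P <- cbind(points[idx, 1] + jit[1], points[idx, 2] + jit[2], 1)
    w1 <- P %*% cw1
    w2 <- P %*% cw2
    w3 <- 1 - w1 - w2
    zhit <- w1 * matrix(zc[1, ], nrow(P), ncol(w1), byrow = TRUE) +
            w2 * matrix(zc[2, ], nrow(P), ncol(w1), byrow = TRUE) +
            w3 * matrix(zc[3, ], nrow(P), ncol(w1), byrow = TRUE)
    cross <- (w1 >= 0) & (w2 >= 0) & (w3 >= 0) & (zhit > points[idx, 3])
    inside[idx] <- (rowSums(cross) %% 2) == 1
  }
  inside
}

#' Analytic ray-ellipsoid exit parameter
#'
#' For a ray starting strictly inside the axis-aligned ellipsoid
#' `(x/a)^2 + (y/b)^2 + (z/c)^2 = 1` (optionally translated), returns the
#' unique positive root `t` of the ray-ellipsoid quadratic, i.e. the exit
#' distance in mm for a unit direction. Serves as the closed-form oracle
#' for mesh ray-casting.
#'
#' @param origin Length-3 numeric, mm; must be strictly inside.
#' @param direction Length-3 numeric; normalised internally.
#' @param semi_axes Length-3 positive numeric, mm.
#' @param center Length-3 numeric, ellipsoid centre, mm.
#' @return Positive scalar `t` in mm.
#' @export
analytic_ellipsoid_intersection <- function(origin, direction, semi_axes,
                                            center = c(0, 0, 0)) {
  o <- (as.numeric(origin) - as.numeric(center)) / as.numeric(semi_axes)
  if (sum(o^2) >= 1) {
    stop("ray origin must lie strictly inside the ellipsoid", call. = FALSE)
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("ray direction is undefined (zero length)", call. = FALSE)
  d <- (as.numeric(direction) / nrm) / as.numeric(semi_axes)
  a <- sum(d^2)
  b <- 2 * sum(o * d)
  cc <- sum(o^2) - 1
  disc <- b^2 - 4 * a * cc
  (-b + sqrt(disc)) / (2 * a)
}

#' Minimum distance from a point to a 3-D polyline
#'
#' Exact minimum Euclidean distance from `p` to the union of segments of an
#' ordered polyline; the orthogonal projection onto each segment is clamped
#' to its endpoints.
#'
#' @param p Length-3 numeric, mm.
#' @param polyline Numeric matrix `k x 3`, ordered vertices, `k >= 2`.
#' @return Non-negative distance in mm.
#' @export
distance_to_polyline <- function(p, polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) {
    stop("polyline must have at least 2 points", call. = FALSE)
  }
  p <- as.numeric(p)
  a <- polyline[-nrow(polyline), , drop = FALSE]
  b <- polyline[-1, , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2, p, `+`)
  tt <- rowSums(ap * ab) / pmax(rowSums(ab^2), .Machine$double.eps)
  tt <- pmin(pmax(tt, 0), 1)
  foot <- a + ab * tt
  sqrt(min(rowSums(sweep(foot, 2, p, `-`)^2)))
}

# Face centroids and circumscribing radii, used to prune the candidate
# faces before the exact point-triangle distance pass.
mesh_distance_index <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cen <- (a + b + c_) / 3
  rad <- sqrt(pmax(rowSums((a - cen)^2),
                   rowSums((b - cen)^2),
                   rowSums((c_ - cen)^2)))
  list(centroids = cen, radii = rad)
}

# Distance from one point to every triangle of a mesh; returns the minimum.
# Region-based point-triangle distance (Ericson), vectorised over faces.
point_to_mesh_distance <- function(p, mesh, index = NULL) {
  p <- as.numeric(p)
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.null(index)) {
    dc <- sqrt(rowSums(sweep(index$centroids, 2, p, `-`)^2))
    bound <- min(dc + index$radii)
    keep <- which(dc - index$radii <= bound)
    f <- f[keep, , drop = FALSE]
  }
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  ap <- sweep(-a, 2, p, `+`)
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-b, 2, p, `+`)
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-c_, 2, p, `+`)
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- pmax(va + vb + vc, .Machine$double.eps)
  u <- vb / denom; w <- vc / denom
  # start from interior solution, then overwrite by Voronoi region
  px <- a + ab * u + ac * w
  reg_a <- d1 <= 0 & d2 <= 0
  px[reg_a, ] <- a[reg_a, ]
  reg_b <- d3 >= 0 & d4 <= d3
  px[reg_b, ] <- b[reg_b, ]
  reg_c <- d6 >= 0 & d5 <= d6
  px[reg_c, ] <- c_[reg_c, ]
  reg_ab <- !reg_a & !reg_b & !reg_c & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(reg_ab)) {
    tt <- d1[reg_ab] / (d1[reg_ab] - d3[reg_ab])
    px[reg_ab, ] <- a[reg_ab, , drop = FALSE] + ab[reg_ab, , drop = FALSE] * tt
  }
  reg_ac <- !reg_a & !reg_b & !reg_c & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(reg_ac)) {
    tt <- d2[reg_ac] / (d2[reg_ac] - d6[reg_ac])
    px[reg_ac, ] <- a[reg_ac, , drop = FALSE] + ac[reg_ac, , drop = FALSE] * tt
  }
  reg_bc <- !reg_a & !reg_b & !reg_c & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(reg_bc)) {
    tt <- (d4[reg_bc] - d3[reg_bc]) /
      ((d4[reg_bc] - d3[reg_bc]) + (d5[reg_bc] - d6[reg_bc]))
    px[reg_bc, ] <- b[reg_bc, , drop = FALSE] +
      (c_[reg_bc, , drop = FALSE] - b[reg_bc, , drop = FALSE]) * tt
  }
  sqrt(min(rowSums(sweep(px, 2, p, `-`)^2)))
}

#' Sampled symmetric Hausdorff distance between two meshes
#'
#' Estimates the Hausdorff distance by measuring the point-to-surface
#' distance from a deterministic subsample of each mesh's vertices to the
#' other mesh and taking the largest. Sampling makes this an
#' underestimate; `n_sample = Inf` uses every vertex.
#'
#' @param mesh_a,mesh_b [oza_mesh()] objects.
#' @param n_sample Max vertices sampled per mesh (evenly strided).
#' @return Distance in mm.
#' @export
hausdorff_distance <- function(mesh_a, mesh_b, n_sample = 500L) {
  stride_sample <- function(m) {
    n <- nrow(m$vertices)
    idx <- if (is.finite(n_sample) && n > n_sample) {
      unique(round(seq(1L, n, length.out = n_sample)))
    } else seq_len(n)
    m$vertices[idx, , drop = FALSE]
  }
  ib <- mesh_distance_index(mesh_b)
  ia <- mesh_distance_index(mesh_a)
  da <- apply(stride_sample(mesh_a), 1, point_to_mesh_distance,
              mesh = mesh_b, index = ib)
  db <- apply(stride_sample(mesh_b), 1, point_to_mesh_distance,
              mesh = mesh_a, index = ia)
  max(max(da), max(db))
}
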