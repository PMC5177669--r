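#' Project the virtual trajectory onto the cranium (point C)
#'
#' Implements the core construction of the analysis: the line from the
#' basilar apex (A) through the internal carotid bifurcation (B) is
#' extended beyond B and intersected with the cranial surface; the exit
#' point through the outer table is point C, the centre of the cranial
#' window a surgeon would need for this corridor. The ray is
#' parameterised by arc length (unit direction), so `t` values are mm
#' with A at `t = 0`.
#'
#' @param A Length-3 numeric, basilar apex, mm; strictly inside the mesh.
#' @param B Length-3 numeric, carotid bifurcation, mm; strictly inside.
#' @param mesh A watertight [oza_mesh()] cranial surface.
#' @param check_inside Verify the A/B preconditions by parity ray-casting
#'   (disable for bulk runs where the generator already guarantees it).
#' @return An object of class `oza_trajectory`: `C` (mm), `t_B`, `t_C`
#'   (mm along the ray), `face_index`, `collinearity_residual` (mm).
#' @export
compute_point_c <- function(A, B, mesh, check_inside = TRUE) {
  A <- as.numeric(A); B <- as.numeric(B)
  sep <- sqrt(sum((B - A)^2))
  if (!is.finite(sep) || sep < 1e-9) {
    stop("A and B coincide: trajectory direction is undefined", call. = FALSE)
  }
  if (check_inside) {
    ins <- points_in_mesh(rbind(A, B), mesh)
    if (!ins[1]) stop("point A is not inside the cranial mesh", call. = FALSE)
    if (!ins[2]) stop("point B is not inside the cranial mesh", call. = FALSE)
  }
  d <- (B - A) / sep
  hits <- ray_mesh_intersections(A, d, mesh)
  if (nrow(hits) == 0) {
    stop("no forward ray-mesh intersection: mesh open or degenerate", call. = FALSE)
  }
  t_C <- hits$t[nrow(hits)]        # largest forward hit = outer-table exit
  face <- hits$face[nrow(hits)]
  if (t_C <= sep) {
    stop("exit point does not lie beyond B; B appears outside the mesh",
         call. = FALSE)
  }
  C <- A + t_C * d
  w <- C - A
  perp <- w - sum(w * d) * d   # perpendicular component, cancellation-safe
  resid <- sqrt(sum(perp^2))
  structure(list(C = C, t_B = sep, t_C = t_C, face_index = face,
                 collinearity_residual = resid),
            class = "oza_trajectory")
}

#' @export
print.oza_trajectory <- function(x, ...) {
  cat(sprintf(
    "<oza_trajectory> C = (%.2f, %.2f, %.2f) mm, t_B = %.2f, t_C = %.2f mm\n",
    x$C[1], x$C[2], x$C[3], x$t_B, x$t_C
  ))
  invisible(x)
}

#' Point C coordinates relative to the external auditory canal
#'
#' The cranial-window centre is conventionally reported from the
#' ipsilateral external auditory canal: a signed vertical offset
#' (superior positive) and a signed occipitofrontal offset (anterior
#' positive).
#'
#' @param trajectory An [compute_point_c()] result.
#' @param eac Length-3 numeric, ipsilateral external auditory canal, mm.
#' @return Named numeric: `vertical_mm`, `occipitofrontal_mm`.
#' @export
point_c_relative_to_eac <- function(trajectory, eac) {
  stopifnot(inherits(trajectory, "oza_trajectory"))
  eac <- as.numeric(eac)
  c(vertical_mm = trajectory$C[3] - eac[3],
    occipitofrontal_mm = trajectory$C[2] - eac[2])
}
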