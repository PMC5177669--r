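#' Height of a point above the dorsum sellae
#'
#' Signed superior distance of a point from the dorsum sellae plane: the
#' z coordinate of the point in the cranial frame. Negative heights mean
#' the point lies below the dorsum sellae (both published ranges include
#' negative values).
#'
#' @param p Length-3 numeric (or `n x 3` matrix), mm.
#' @param frame A [cranial_frame()].
#' @return Signed height(s) in mm.
#' @export
height_above_dorsum <- function(p, frame = cranial_frame()) {
  p <- rbind(p)
  local <- sweep(p, 2, frame$origin, `-`) %*% t(frame$axes)
  unname(local[, 3])
}

#' Lateral width of a point from the midline
#'
#' Perpendicular distance of a point from the midsagittal plane (x = 0 in
#' the cranial frame); always non-negative and invariant under mirror
#' reflection.
#'
#' @param p Length-3 numeric (or `n x 3` matrix), mm.
#' @param frame A [cranial_frame()].
#' @return Non-negative width(s) in mm.
#' @export
width_from_midline <- function(p, frame = cranial_frame()) {
  p <- rbind(p)
  local <- sweep(p, 2, frame$origin, `-`) %*% t(frame$axes)
  unname(abs(local[, 1]))
}

#' All craniometric measurements for one trajectory
#'
#' Produces the five published quantities for one subject-side — heights
#' of A and B above the dorsum sellae, lateral width of B, and the
#' distances from point C to the zygomatic arch (C-Z) and to the lateral
#' canthus (C-L) — plus point C's coordinates relative to the ipsilateral
#' external auditory canal. Distances are straight-line 3-D Euclidean
#' chords. C-Z uses the full arch polyline by default; `cz_mode =
#' "midpoint"` measures to the mid-zygomatic point instead.
#'
#' @param anatomy An [generate_skull()] model carrying the landmark set.
#' @param trajectory An [compute_point_c()] result for this side.
#' @param side `"left"` or `"right"`.
#' @param A,B Length-3 numeric vascular points, mm.
#' @param subject_id Identifier copied into the record.
#' @param cz_mode `"polyline"` (default) or `"midpoint"`.
#' @return One-row tibble: `subject_id`, `side`, `height_A_mm`,
#'   `height_B_mm`, `width_B_mm`, `cz_mm`, `cl_mm`, `c_vertical_mm`,
#'   `c_occipitofrontal_mm`.
#' @export
measure_all <- function(anatomy, trajectory, side, A, B, subject_id = 1L,
                        cz_mode = c("polyline", "midpoint")) {
  stopifnot(inherits(anatomy, "anatomy_model"),
            inherits(trajectory, "oza_trajectory"))
  side <- match.arg(side, c("left", "right"))
  cz_mode <- match.arg(cz_mode)
  lm <- anatomy$landmarks
  for (nm in c("zygomatic_arch", "lateral_canthus", "eac")) {
    if (is.null(lm[[nm]][[side]])) {
      stop("missing landmark: ", nm, " (", side, ")", call. = FALSE)
    }
  }
  frame <- anatomy$frame
  arch <- lm$zygomatic_arch[[side]]
  cz <- if (cz_mode == "polyline") {
    distance_to_polyline(trajectory$C, arch)
  } else {
    mid <- arch[ceiling(nrow(arch) / 2), ]
    sqrt(sum((trajectory$C - mid)^2))
  }
  cl <- sqrt(sum((trajectory$C - lm$lateral_canthus[[side]])^2))
  rel <- point_c_relative_to_eac(trajectory, lm$eac[[side]])
  tibble::tibble(
    subject_id = subject_id,
    side = side,
    height_A_mm = height_above_dorsum(A, frame),
    height_B_mm = height_above_dorsum(B, frame),
    width_B_mm = width_from_midline(B, frame),
    cz_mm = cz,
    cl_mm = cl,
    c_vertical_mm = unname(rel["vertical_mm"]),
    c_occipitofrontal_mm = unname(rel["occipitofrontal_mm"])
  )
}

#' Simulate a measured cohort end-to-end
#'
#' Generates (or reuses) a skull phantom, samples vascular point pairs
#' from the calibrated cohort distributions, computes the trajectory exit
#' point C for every sample, and measures all craniometric quantities.
#' This is the synthetic analogue of measuring a CT-angiography cohort.
#'
#' @param cohort A [cohort_params()] record.
#' @param skull A [skull_params()] record, or an existing
#'   [generate_skull()] model to reuse.
#' @param seed Integer seed; the whole table is a pure function of
#'   `(cohort, skull, seed)`.
#' @param cz_mode Passed to [measure_all()].
#' @return A cohort tibble with the [measure_all()] columns, one row per
#'   subject-side.
#' @export
simulate_cohort <- function(cohort = cohort_params(), skull = skull_params(),
                            seed = 1L, cz_mode = "polyline") {
  anatomy <- if (inherits(skull, "anatomy_model")) skull else
    generate_skull(skull, seed = seed)
  pts <- sample_vascular_points(anatomy, cohort, seed = seed)
  purrr::pmap_dfr(pts, function(subject_id, side, height_A_mm, height_B_mm,
                                width_B_mm, ax, ay, az, bx, by, bz) {
    A <- c(ax, ay, az)
    B <- c(bx, by, bz)
    traj <- compute_point_c(A, B, anatomy$mesh, check_inside = FALSE)
    measure_all(anatomy, traj, side, A, B, subject_id = subject_id,
                cz_mode = cz_mode)
  })
}

#' Read / write a cohort table as CSV
#'
#' Fixed-header CSV round-trip for cohort tables
#' (`subject_id, side, height_A_mm, ..., c_occipitofrontal_mm`); values
#' are written in full precision so read-back is lossless.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = readr::col_integer(),
                    side = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
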