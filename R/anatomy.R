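#' Cranial coordinate frame
#'
#' All measurements use a right-handed frame anchored at the dorsum sellae
#' apex: +x points laterally toward the ipsilateral side, +y anteriorly,
#' +z superiorly. The midsagittal plane is x = 0, so "height" of a
#' vascular point is its z coordinate and "width" its |x|.
#'
#' @param origin Length-3 numeric, dorsum sellae position in mm.
#' @param axes 3x3 orthonormal rotation matrix (rows = frame axes).
#' @param side `"left"` or `"right"`: which hemisphere is ipsilateral.
#' @return An object of class `cranial_frame`.
#' @export
cranial_frame <- function(origin = c(0, 0, 0), axes = diag(3), side = "right") {
  side <- match.arg(side, c("left", "right"))
  axes <- as.matrix(axes)
  if (max(abs(axes %*% t(axes) - diag(3))) > 1e-8) {
    stop("frame axes must be orthonormal", call. = FALSE)
  }
  structure(list(origin = as.numeric(origin), axes = axes, side = side),
            class = "cranial_frame")
}

#' Skull phantom parameters
#'
#' The synthetic cranium is a triangulated ellipsoid whose centre sits
#' `center_height` mm above the dorsum sellae, so the frame origin lies in
#' the skull-base region. Default semi-axes 70 (lateral) x 90 (AP) x 65
#' (SI) mm give an adult-sized vault. Landmarks are placed at fixed
#' directions on the unit sphere and scaled with the semi-axes, so they
#' stay exactly on the analytic surface for any skull size.
#'
#' @param semi_axes Length-3 positive numeric, mm.
#' @param center_height Height of the ellipsoid centre above the dorsum
#'   sellae, mm; default scales with the SI semi-axis (20 mm at default).
#' @param subdivisions Icosphere refinement rounds for the mesh.
#' @return A named list of class `skull_params`.
#' @export
skull_params <- function(semi_axes = c(70, 90, 65), center_height = NULL,
                         subdivisions = 4) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3 || any(!is.finite(semi_axes)) || any(semi_axes <= 0)) {
    stop("semi_axes must be three positive numbers (mm)", call. = FALSE)
  }
  if (subdivisions < 3) stop("subdivisions must be >= 3", call. = FALSE)
  if (is.null(center_height)) center_height <- semi_axes[3] * 20 / 65
  structure(list(semi_axes = semi_axes, center_height = center_height,
                 subdivisions = as.integer(subdivisions)),
            class = "skull_params")
}

# Unit-sphere directions of the surface landmarks (y and z components as
# fractions of the AP and SI semi-axes at the default skull; x recovered
# from the sphere equation). Arch runs posterior -> anterior at the level
# just above the external auditory canal, as the bony arch does.
.landmark_units <- function() {
  uy_arch <- seq(0, 45, length.out = 5) / 90
  list(
    eac = c(uy = -5 / 90, uz = -45 / 65),
    lateral_canthus = c(uy = 70 / 90, uz = -20 / 65),
    arch = cbind(uy = uy_arch, uz = rep(-40 / 65, 5))
  )
}

.surface_point <- function(uy, uz, semi_axes, center) {
  ux2 <- 1 - uy^2 - uz^2
  if (any(ux2 <= 0)) stop("landmark direction off the unit sphere", call. = FALSE)
  cbind(sqrt(ux2) * semi_axes[1],
        uy * semi_axes[2] + center[2],
        uz * semi_axes[3] + center[3]) + rep(c(center[1], 0, 0), each = length(uy))
}

#' Generate a synthetic cranial phantom
#'
#' Builds a watertight ellipsoid skull mesh with the full landmark set
#' (dorsum sellae, external auditory canals, lateral canthi, zygomatic
#' arch polylines, midsagittal normal) placed parametrically on the
#' analytic surface, mirror-symmetric about x = 0. The result is a pure
#' function of `(params, seed)`: identical inputs give bit-identical
#' vertex arrays.
#'
#' @param params A [skull_params()] record.
#' @param seed Integer, stored in the model for provenance (the skull
#'   itself is deterministic; downstream sampling consumes the seed).
#' @param side Ipsilateral side of the frame, `"right"` or `"left"`.
#' @return An object of class `anatomy_model`: `mesh`, `frame`,
#'   `landmarks`, `vessels` (NULL until sampled), `params`, `seed`.
#' @export
generate_skull <- function(params = skull_params(), seed = 0L, side = "right") {
  if (!inherits(params, "skull_params")) params <- do.call(skull_params, params)
  a <- params$semi_axes
  center <- c(0, 0, params$center_height)
  mesh <- ellipsoid_mesh(a, center = center, subdivisions = params$subdivisions)
  u <- .landmark_units()
  eac_r <- .surface_point(u$eac["uy"], u$eac["uz"], a, center)
  lc_r <- .surface_point(u$lateral_canthus["uy"], u$lateral_canthus["uz"], a, center)
  arch_r <- .surface_point(u$arch[, "uy"], u$arch[, "uz"], a, center)
  mirror <- function(p) {
    p <- rbind(p)
    p[, 1] <- -p[, 1]
    p
  }
  landmarks <- list(
    dorsum_sellae = c(0, 0, 0),
    eac = list(right = as.numeric(eac_r), left = as.numeric(mirror(eac_r))),
    lateral_canthus = list(right = as.numeric(lc_r), left = as.numeric(mirror(lc_r))),
    zygomatic_arch = list(right = arch_r, left = mirror(arch_r)),
    midsagittal_normal = c(1, 0, 0)
  )
  structure(list(
    mesh = mesh,
    frame = cranial_frame(side = side),
    landmarks = landmarks,
    vessels = NULL,
    params = params,
    seed = as.integer(seed)
  ), class = "anatomy_model")
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat(sprintf(
    "<anatomy_model> semi-axes %s mm, %d faces, %s vessels\n",
    paste(x$params$semi_axes, collapse = " x "), nrow(x$mesh$faces),
    if (is.null(x$vessels)) "no" else nrow(x$vessels)
  ))
  invisible(x)
}

#' Cohort simulation parameters
#'
#' Defaults reproduce the published 80-sample cohort statistics: basilar
#' apex height 4.9 +/- 3.8 mm (range -5 to 10.5), carotid bifurcation
#' height 5.7 +/- 3.1 mm (range -1.4 to 15) and lateral width 15.7 +/- 3.4
#' mm (range 8.4 to 35.1), all relative to the dorsum sellae / midline.
#' Each quantity is drawn from a range-truncated normal whose underlying
#' parameters are moment-matched so that the *truncated* distribution has
#' the stated mean and SD (see [fit_truncated_normal()]).
#'
#' @param n Number of samples (sides); must be >= 2.
#' @param height_A,height_B,width_B Length-4 numeric `(mean, sd, min, max)`
#'   in mm.
#' @param a_posterior_offset Mean anteroposterior position of the basilar
#'   apex, mm (negative = posterior to the dorsum sellae).
#' @param b_anterior_offset Mean anteroposterior position of the carotid
#'   bifurcation, mm.
#' @param jitter_sd Gaussian jitter SD on the anteroposterior offsets, mm.
#' @param mirror_sides If `TRUE`, consecutive samples of a subject are
#'   mirror images; default treats the two sides as independent draws.
#' @return A named list of class `cohort_params`.
#' @export
cohort_params <- function(n = 80L,
                          height_A = c(mean = 4.9, sd = 3.8, min = -5, max = 10.5),
                          height_B = c(mean = 5.7, sd = 3.1, min = -1.4, max = 15),
                          width_B = c(mean = 15.7, sd = 3.4, min = 8.4, max = 35.1),
                          a_posterior_offset = -8,
                          b_anterior_offset = 10,
                          jitter_sd = 2,
                          mirror_sides = FALSE) {
  n <- as.integer(n)
  if (n < 2) stop("cohort size n must be >= 2", call. = FALSE)
  for (nm in c("height_A", "height_B", "width_B")) {
    q <- as.numeric(get(nm))
    if (length(q) != 4) stop(nm, " must be (mean, sd, min, max)", call. = FALSE)
    if (q[2] <= 0) stop(nm, ": sd must be > 0", call. = FALSE)
    if (q[3] >= q[4]) stop(nm, ": min must be < max", call. = FALSE)
  }
  structure(list(
    n = n,
    height_A = stats::setNames(as.numeric(height_A), c("mean", "sd", "min", "max")),
    height_B = stats::setNames(as.numeric(height_B), c("mean", "sd", "min", "max")),
    width_B = stats::setNames(as.numeric(width_B), c("mean", "sd", "min", "max")),
    a_posterior_offset = a_posterior_offset,
    b_anterior_offset = b_anterior_offset,
    jitter_sd = jitter_sd,
    mirror_sides = isTRUE(mirror_sides)
  ), class = "cohort_params")
}

# Mean and SD of a normal(mu, sigma) truncated to [lo, hi].
truncated_normal_moments <- function(mu, sigma, lo, hi) {
  mu <- unname(mu); sigma <- unname(sigma); lo <- unname(lo); hi <- unname(hi)
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z < 1e-300) return(c(mean = (lo + hi) / 2, sd = (hi - lo) / sqrt(12)))
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Moment-matched truncated normal parameters
#'
#' Finds the underlying normal `(mu, sigma)` such that its truncation to
#' `[lo, hi]` has the requested mean and SD. This makes cohort draws
#' reproduce published summary statistics exactly in expectation instead
#' of inheriting the downward/upward bias an asymmetric truncation
#' imposes on naive parameters. Deterministic Nelder-Mead fit.
#'
#' @param target_mean,target_sd Moments the truncated distribution must have.
#' @param lo,hi Truncation bounds, mm.
#' @return List with `mu`, `sigma`, and achieved `moments`.
#' @export
fit_truncated_normal <- function(target_mean, target_sd, lo, hi) {
  target_mean <- unname(target_mean); target_sd <- unname(target_sd)
  lo <- unname(lo); hi <- unname(hi)
  if (hi - lo < 1e-9) {
    return(list(mu = target_mean, sigma = target_sd,
                moments = c(mean = (lo + hi) / 2, sd = 0)))
  }
  obj <- function(par) {
    m <- truncated_normal_moments(par[1], exp(par[2]), lo, hi)
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  list(mu = mu, sigma = sigma,
       moments = truncated_normal_moments(mu, sigma, lo, hi))
}

#' Draw from a range-truncated normal by inverse transform
#'
#' Every draw lies in `[lo, hi]` by construction. With
#' `moment_match = TRUE` (default) the underlying parameters come from
#' [fit_truncated_normal()], so the sample mean/SD target the requested
#' moments; otherwise the requested `(mean, sd)` parameterise the
#' untruncated normal directly.
#'
#' @param n Number of draws.
#' @param mean,sd,lo,hi Target moments and truncation range, mm.
#' @param moment_match Logical, see above.
#' @return Numeric vector of length `n`.
#' @export
rtruncated_normal <- function(n, mean, sd, lo, hi, moment_match = TRUE) {
  mean <- unname(mean); sd <- unname(sd); lo <- unname(lo); hi <- unname(hi)
  if (moment_match) {
    fit <- fit_truncated_normal(mean, sd, lo, hi)
    mu <- fit$mu; sigma <- fit$sigma
  } else {
    mu <- mean; sigma <- sd
  }
  plo <- stats::pnorm(lo, mu, sigma)
  phi <- stats::pnorm(hi, mu, sigma)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mu, sigma), lo), hi)
}

#' Sample vascular point pairs for a cohort
#'
#' Draws basilar-apex (A) and carotid-bifurcation (B) positions whose
#' height/width distributions follow the cohort parameters. A sits
#' near-midline (|x| <= 2 mm) at the posterior offset; B sits at the
#' sampled lateral width on the sample's side at the anterior offset.
#' Sides alternate right/left within subjects (independent draws unless
#' `mirror_sides`). Every point is verified to lie strictly inside the
#' skull mesh; an out-of-mesh draw is retried and eventually raises an
#' error naming the offending quantity.
#'
#' @param anatomy An [generate_skull()] model.
#' @param cohort A [cohort_params()] record.
#' @param seed Integer RNG seed; the draw is a pure function of
#'   `(anatomy, cohort, seed)`.
#' @param max_retries Resampling attempts per point before failing.
#' @return A tibble with one row per sample: `subject_id`, `side`,
#'   `height_A_mm`, `height_B_mm`, `width_B_mm`, and the A/B coordinates
#'   `ax, ay, az, bx, by, bz` (mm).
#' @export
sample_vascular_points <- function(anatomy, cohort = cohort_params(), seed = 1L,
                                   max_retries = 25L) {
  stopifnot(inherits(anatomy, "anatomy_model"))
  if (!inherits(cohort, "cohort_params")) cohort <- do.call(cohort_params, cohort)
  n <- cohort$n
  with_seed(seed, {
    hA <- rtruncated_normal(n, cohort$height_A["mean"], cohort$height_A["sd"],
                            cohort$height_A["min"], cohort$height_A["max"])
    hB <- rtruncated_normal(n, cohort$height_B["mean"], cohort$height_B["sd"],
                            cohort$height_B["min"], cohort$height_B["max"])
    wB <- rtruncated_normal(n, cohort$width_B["mean"], cohort$width_B["sd"],
                            cohort$width_B["min"], cohort$width_B["max"])
    xA <- rtruncated_normal(n, 0, 1, -2, 2, moment_match = FALSE)
    yA <- stats::rnorm(n, cohort$a_posterior_offset, cohort$jitter_sd)
    yB <- stats::rnorm(n, cohort$b_anterior_offset, cohort$jitter_sd)
    side <- rep(c("right", "left"), length.out = n)
    if (cohort$mirror_sides) {
      pair <- (seq_len(n) + 1L) %/% 2L
      first <- !duplicated(pair)
      for (v in c("hA", "hB", "wB", "xA", "yA", "yB")) {
        vals <- get(v)
        vals <- vals[first][pair]
        assign(v, vals)
      }
    }
    sgn <- ifelse(side == "right", 1, -1)
    A <- cbind(xA, yA, hA)
    B <- cbind(sgn * wB, yB, hB)
    inside_A <- points_in_mesh(A, anatomy$mesh)
    inside_B <- points_in_mesh(B, anatomy$mesh)
    for (i in seq_len(n)) {
      tries <- 0L
      while (!inside_A[i] || !inside_B[i]) {
        tries <- tries + 1L
        if (tries > max_retries) {
          bad <- if (!inside_A[i]) "height_A (point A placement)" else
            "width_B/height_B (point B placement)"
          stop("sampled point outside the skull after ", max_retries,
               " retries; check ", bad, call. = FALSE)
        }
        hA[i] <- rtruncated_normal(1, cohort$height_A["mean"], cohort$height_A["sd"],
                                   cohort$height_A["min"], cohort$height_A["max"])
        hB[i] <- rtruncated_normal(1, cohort$height_B["mean"], cohort$height_B["sd"],
                                   cohort$height_B["min"], cohort$height_B["max"])
        wB[i] <- rtruncated_normal(1, cohort$width_B["mean"], cohort$width_B["sd"],
                                   cohort$width_B["min"], cohort$width_B["max"])
        A[i, ] <- c(rtruncated_normal(1, 0, 1, -2, 2, moment_match = FALSE),
                    stats::rnorm(1, cohort$a_posterior_offset, cohort$jitter_sd),
                    hA[i])
        B[i, ] <- c(sgn[i] * wB[i],
                    stats::rnorm(1, cohort$b_anterior_offset, cohort$jitter_sd),
                    hB[i])
        inside_A[i] <- points_in_mesh(A[i, ], anatomy$mesh)
        inside_B[i] <- points_in_mesh(B[i, ], anatomy$mesh)
      }
    }
    tibble::tibble(
      subject_id = (seq_len(n) + 1L) %/% 2L,
      side = side,
      height_A_mm = hA, height_B_mm = hB, width_B_mm = wB,
      ax = A[, 1], ay = A[, 2], az = A[, 3],
      bx = B[, 1], by = B[, 2], bz = B[, 3]
    )
  })
}
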