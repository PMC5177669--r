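test_that("landmarks sit on the skull surface and mirror across the midline", {
  m <- generate_skull(skull_params(c(70, 90, 65)))
  lm <- m$landmarks
  pts <- rbind(
    lm$eac$right, lm$eac$left,
    lm$lateral_canthus$right, lm$lateral_canthus$left,
    lm$zygomatic_arch$right, lm$zygomatic_arch$left
  )
  # signed distance to the analytic ellipsoid (radial bound on |phi - 1|)
  u <- sweep(sweep(pts, 2, default_center, `-`), 2, c(70, 90, 65), `/`)
  rad <- sqrt(rowSums(u^2))
  expect_true(all(abs(rad - 1) * min(c(70, 90, 65)) < 2))
  # dorsum sellae is interior (skull base), not a surface point
  expect_true(points_in_mesh(lm$dorsum_sellae, m$mesh))
  # mirror symmetry
  flip <- function(p) {
    p <- rbind(p); p[, 1] <- -p[, 1]; p
  }
  expect_lt(max(abs(flip(lm$eac$right) - rbind(lm$eac$left))), 1e-6)
  expect_lt(max(abs(flip(lm$lateral_canthus$right) - rbind(lm$lateral_canthus$left))), 1e-6)
  expect_lt(max(abs(flip(lm$zygomatic_arch$right) - lm$zygomatic_arch$left)), 1e-6)
  # arch polylines run posterior -> anterior
  expect_true(all(diff(lm$zygomatic_arch$right[, 2]) > 0))
  expect_true(all(diff(lm$zygomatic_arch$left[, 2]) > 0))
})

test_that("moment-matched truncated normal reproduces target moments", {
  # oracle: numerical integration of the truncated density
  int_moments <- function(mu, sigma, lo, hi) {
    z <- stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
    m1 <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma) / z,
                           lo, hi, rel.tol = 1e-10)$value
    m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mu, sigma) / z,
                           lo, hi, rel.tol = 1e-10)$value
    c(mean = m1, sd = sqrt(m2 - m1^2))
  }
  cases <- list(c(4.9, 3.8, -5, 10.5), c(5.7, 3.1, -1.4, 15),
                c(15.7, 3.4, 8.4, 35.1))
  for (q in cases) {
    fit <- fit_truncated_normal(q[1], q[2], q[3], q[4])
    oracle <- int_moments(fit$mu, fit$sigma, q[3], q[4])
    expect_equal(unname(oracle["mean"]), q[1], tolerance = 1e-5)
    expect_equal(unname(oracle["sd"]), q[2], tolerance = 1e-5)
  }
})

test_that("truncated draws always respect the range, even a degenerate one", {
  withr::local_seed(42)
  x <- rtruncated_normal(500, 5.7, 3.1, -1.4, 15)
  expect_true(all(x >= -1.4 & x <= 15))
  eps <- 1e-6
  for (q in list(c(4.9, 3.8), c(5.7, 3.1), c(15.7, 3.4))) {
    y <- rtruncated_normal(200, q[1], q[2], q[1], q[1] + eps)
    expect_true(all(y >= q[1] & y <= q[1] + eps))
  }
})

test_that("carotid-bifurcation height draws hit the published mean", {
  m <- small_skull  # distribution code does not depend on the mesh size
  pts <- sample_vascular_points(m, cohort_params(n = 2000), seed = 1)
  expect_lt(abs(mean(pts$height_B_mm) - 5.7), 0.2)
})

test_that("an 80-sample cohort yields point pairs strictly inside the skull", {
  pts <- sample_vascular_points(default_skull, cohort_params(n = 80), seed = 7)
  expect_identical(nrow(pts), 80L)
  A <- cbind(pts$ax, pts$ay, pts$az)
  B <- cbind(pts$bx, pts$by, pts$bz)
  expect_true(all(points_in_mesh(A, default_skull$mesh)))
  expect_true(all(points_in_mesh(B, default_skull$mesh)))
  # basilar apex is near-midline, A and B well separated
  expect_true(all(abs(pts$ax) <= 2))
  expect_true(all(sqrt(rowSums((B - A)^2)) > 1))
  # B's lateral position is on the labelled side
  expect_true(all(sign(pts$bx) == ifelse(pts$side == "right", 1, -1)))
})

test_that("vascular sampling is deterministic in (params, seed)", {
  a <- sample_vascular_points(small_skull, cohort_params(n = 12), seed = 3)
  b <- sample_vascular_points(small_skull, cohort_params(n = 12), seed = 3)
  expect_identical(a, b)
  c_ <- sample_vascular_points(small_skull, cohort_params(n = 12), seed = 4)
  expect_false(identical(a$height_A_mm, c_$height_A_mm))
})

test_that("mirrored-sides mode duplicates subjects across hemispheres", {
  pts <- sample_vascular_points(small_skull,
                                cohort_params(n = 10, mirror_sides = TRUE),
                                seed = 5)
  odd <- pts[seq(1, 9, by = 2), ]
  even <- pts[seq(2, 10, by = 2), ]
  expect_equal(odd$height_A_mm, even$height_A_mm)
  expect_equal(odd$bx, -even$bx)
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohort_params(n = 1), "n must be")
  expect_error(cohort_params(height_A = c(4.9, 0, -5, 10.5)), "sd must be")
  expect_error(cohort_params(width_B = c(15.7, 3.4, 20, 10)), "min must be")
})
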