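test_that("heights are signed z offsets from the dorsum sellae", {
  fr <- cranial_frame()
  expect_equal(height_above_dorsum(c(0, 0, 0), fr), 0)
  expect_equal(height_above_dorsum(c(5, 9, 12.3), fr), 12.3)
  expect_equal(height_above_dorsum(c(2, 3, -1.4), fr), -1.4)  # below: negative
})

test_that("width from midline is a reflection-invariant |x|", {
  fr <- cranial_frame()
  expect_equal(width_from_midline(c(0, 12, 5), fr), 0)
  expect_equal(width_from_midline(c(-15.7, 3, 3), fr), 15.7)
  withr::local_seed(8)
  p <- matrix(stats::rnorm(30, sd = 20), ncol = 3)
  q <- p; q[, 1] <- -q[, 1]
  expect_equal(width_from_midline(p, fr), width_from_midline(q, fr))
})

test_that("point-to-polyline distance matches a dense-sampling oracle", {
  seg <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(distance_to_polyline(c(3, 0, 0), seg), 0)
  expect_equal(distance_to_polyline(c(5, 0, 7), seg), 7)       # foot of perpendicular
  expect_equal(distance_to_polyline(c(-3, 4, 0), seg), 5)      # clamped to endpoint
  expect_error(distance_to_polyline(c(0, 0, 0), rbind(c(1, 1, 1))), "at least 2")
  withr::local_seed(13)
  poly <- matrix(stats::rnorm(15, sd = 30), ncol = 3)
  dense <- do.call(rbind, lapply(1:4, function(i) {
    tt <- seq(0, 1, length.out = 25000)
    outer(1 - tt, poly[i, ]) + outer(tt, poly[i + 1, ])
  }))
  for (i in 1:10) {
    p <- stats::rnorm(3, sd = 40)
    brute <- sqrt(min(rowSums(sweep(dense, 2, p, `-`)^2)))
    expect_lt(abs(distance_to_polyline(p, poly) - brute), 1e-3)
  }
})

test_that("mirrored vascular points give mirrored measurement records", {
  m <- default_skull
  A <- c(0.7, -8, 4.9); B <- c(15.7, 10, 5.7)
  Am <- A * c(-1, 1, 1); Bm <- B * c(-1, 1, 1)
  right <- measure_all(m, compute_point_c(A, B, m$mesh), "right", A, B)
  left <- measure_all(m, compute_point_c(Am, Bm, m$mesh), "left", Am, Bm)
  for (col in c("height_A_mm", "height_B_mm", "width_B_mm", "cz_mm", "cl_mm",
                "c_vertical_mm", "c_occipitofrontal_mm")) {
    expect_equal(right[[col]], left[[col]], tolerance = 1e-9)
  }
})

test_that("C at the lateral canthus gives zero C-L distance", {
  m <- default_skull
  traj <- structure(list(C = m$landmarks$lateral_canthus$right, t_B = 10,
                         t_C = 50, face_index = 1L, collinearity_residual = 0),
                    class = "oza_trajectory")
  rec <- measure_all(m, traj, "right", c(0, -8, 5), c(15, 10, 6))
  expect_equal(rec$cl_mm, 0)
  expect_gte(rec$cz_mm, 0)
})

test_that("C-Z and C-L are continuous in C", {
  m <- default_skull
  A <- c(0, -8, 5); B <- c(16, 10, 6)
  tr <- compute_point_c(A, B, m$mesh)
  base <- measure_all(m, tr, "right", A, B)
  withr::local_seed(17)
  for (i in 1:10) {
    shift <- stats::rnorm(3)
    shift <- 0.1 * shift / sqrt(sum(shift^2))
    tr2 <- tr; tr2$C <- tr$C + shift
    rec <- measure_all(m, tr2, "right", A, B)
    expect_lt(abs(rec$cz_mm - base$cz_mm), 0.2)
    expect_lt(abs(rec$cl_mm - base$cl_mm), 0.2)
  }
})

test_that("mid-zygomatic point mode measures at least the polyline distance", {
  m <- default_skull
  A <- c(0, -8, 5); B <- c(16, 10, 6)
  tr <- compute_point_c(A, B, m$mesh)
  poly <- measure_all(m, tr, "right", A, B, cz_mode = "polyline")
  midp <- measure_all(m, tr, "right", A, B, cz_mode = "midpoint")
  expect_gte(midp$cz_mm, poly$cz_mm)
})

test_that("a missing landmark is reported by name", {
  m <- default_skull
  m$landmarks$lateral_canthus$left <- NULL
  traj <- structure(list(C = c(10, 10, 10), t_B = 1, t_C = 2, face_index = 1L,
                         collinearity_residual = 0), class = "oza_trajectory")
  expect_error(measure_all(m, traj, "left", c(0, 0, 0), c(1, 1, 1)),
               "lateral_canthus")
})

test_that("an 80-sample simulated cohort is complete and round-trips via CSV", {
  co <- simulate_cohort(cohort_params(n = 80), default_skull, seed = 7)
  expect_identical(nrow(co), 80L)
  expect_named(co, c("subject_id", "side", "height_A_mm", "height_B_mm",
                     "width_B_mm", "cz_mm", "cl_mm", "c_vertical_mm",
                     "c_occipitofrontal_mm"))
  expect_false(anyNA(co))
  expect_true(all(co$cz_mm >= 0 & co$cl_mm >= 0 & co$width_B_mm >= 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  expect_equal(as.data.frame(read_cohort_csv(path)), as.data.frame(co))
})
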