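test_that("central ray on a sphere exits at the radius", {
  sphere <- ellipsoid_mesh(c(100, 100, 100), subdivisions = 4)
  tr <- compute_point_c(c(0, 0, 0), c(1, 0, 0), sphere)
  expect_equal(tr$t_C, 100, tolerance = 1e-3)
  expect_equal(tr$C, c(100, 0, 0), tolerance = 0.2)
  expect_lt(tr$collinearity_residual, 1e-6)
})

test_that("analytic ellipsoid intersection satisfies its closed form", {
  # sphere: any interior origin along an axis
  expect_equal(analytic_ellipsoid_intersection(c(0, 0, 0), c(0, 1, 0),
                                               c(50, 50, 50)), 50)
  expect_equal(analytic_ellipsoid_intersection(c(0, 0, 0), c(0, 0, 1),
                                               c(70, 90, 65)), 65)
  expect_error(analytic_ellipsoid_intersection(c(80, 0, 0), c(1, 0, 0),
                                               c(70, 90, 65)), "inside")
  # residual property: returned point satisfies the implicit equation
  withr::local_seed(11)
  for (i in 1:50) {
    o <- runif_in_ellipsoid(1, c(70, 90, 65))
    d <- stats::rnorm(3)
    tt <- analytic_ellipsoid_intersection(o, d, c(70, 90, 65))
    p <- o + tt * d / sqrt(sum(d^2))
    expect_lt(abs(sum((p / c(70, 90, 65))^2) - 1), 1e-10)
  }
})

test_that("mesh ray-casting agrees with the analytic ellipsoid oracle", {
  mesh <- ellipsoid_mesh(c(70, 90, 65), subdivisions = 4)
  tr <- compute_point_c(c(0, -8, 5), c(16, 10, 6), mesh)
  t_true <- analytic_ellipsoid_intersection(
    c(0, -8, 5), c(16, 18, 1), c(70, 90, 65)
  )
  expect_lt(abs(tr$t_C - t_true), 0.5)
  withr::local_seed(21)
  for (i in 1:100) {
    A <- runif_in_ellipsoid(1, c(70, 90, 65))
    B <- runif_in_ellipsoid(1, c(70, 90, 65))
    if (sqrt(sum((B - A)^2)) < 1) next
    tr <- compute_point_c(A, B, mesh, check_inside = FALSE)
    t_true <- analytic_ellipsoid_intersection(A, B - A, c(70, 90, 65))
    expect_lt(abs(tr$t_C - t_true), 0.5)
  }
})

test_that("discretization error shrinks monotonically with refinement", {
  A <- c(0, -8, 5); B <- c(16, 10, 6)
  t_true <- analytic_ellipsoid_intersection(A, B - A, c(70, 90, 65))
  errs <- sapply(3:5, function(s) {
    mesh <- ellipsoid_mesh(c(70, 90, 65), subdivisions = s)
    abs(compute_point_c(A, B, mesh, check_inside = FALSE)$t_C - t_true)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("every trajectory is collinear and exits beyond B", {
  withr::local_seed(31)
  mesh <- default_skull$mesh
  semi <- default_skull$params$semi_axes
  for (i in 1:40) {
    A <- runif_in_ellipsoid(1, semi, default_center, shrink = 0.8)
    B <- runif_in_ellipsoid(1, semi, default_center, shrink = 0.8)
    if (sqrt(sum((B - A)^2)) < 1) next
    tr <- compute_point_c(A, B, mesh, check_inside = FALSE)
    expect_lt(tr$collinearity_residual, 1e-6)
    expect_gt(tr$t_C, tr$t_B)
    expect_gt(tr$t_B, 0)
    # C lies on the mesh surface (distance to intersected face ~ 0)
    face <- tr$face_index
    tri <- oza_mesh(mesh$vertices, mesh$faces[face, , drop = FALSE])
    expect_lt(ozaplan:::point_to_mesh_distance(tr$C, tri), 1e-3)
  }
})

test_that("degenerate trajectory inputs raise informative errors", {
  mesh <- small_skull$mesh
  expect_error(compute_point_c(c(1, 2, 3), c(1, 2, 3), mesh), "coincide")
  expect_error(compute_point_c(c(0, 0, 5), c(500, 0, 0), mesh), "not inside")
  expect_error(compute_point_c(c(500, 0, 0), c(0, 0, 5), mesh), "not inside")
})

test_that("raising the apex lowers C; raising the bifurcation raises C", {
  mesh <- default_skull$mesh
  zc <- function(hA, hB) {
    compute_point_c(c(0, -8, hA), c(15.7, 10, hB), mesh,
                    check_inside = FALSE)$C[3]
  }
  for (hA in c(-4, 0, 4, 8)) {
    expect_lt(zc(hA + 1, 5.7), zc(hA, 5.7))
  }
  for (hB in c(-1, 3, 7, 12)) {
    expect_gt(zc(4.9, hB + 1), zc(4.9, hB))
  }
})

test_that("point C is reported relative to the external auditory canal", {
  traj <- structure(list(C = c(10, 40, 70), t_B = 10, t_C = 50,
                         face_index = 1L, collinearity_residual = 0),
                    class = "oza_trajectory")
  expect_equal(point_c_relative_to_eac(traj, c(10, 40, 70)),
               c(vertical_mm = 0, occipitofrontal_mm = 0))
  expect_equal(point_c_relative_to_eac(traj, c(10, 10, 10)),
               c(vertical_mm = 60, occipitofrontal_mm = 30))
})
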