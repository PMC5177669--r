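test_that("the approach rule classifies the canonical distance pairs", {
  expect_identical(as.character(classify_oza(15, 29.5)$label), "oza_recommended")
  expect_identical(as.character(classify_oza(57, 47.9)$label), "pterional_sufficient")
  expect_identical(as.character(classify_oza(36, 31)$label), "indeterminate")
  # boundary values fall to indeterminate, never to a recommendation
  expect_identical(as.character(classify_oza(30, 30)$label), "indeterminate")
  expect_identical(as.character(classify_oza(40, 40)$label), "indeterminate")
  expect_identical(as.character(classify_oza(29.9, 31)$label), "indeterminate")
  expect_error(classify_oza(-1, 10), "non-negative")
  expect_error(classify_oza(10, 10, low_mm = 40, high_mm = 30), "low_mm")
})

test_that("the decision partition is exhaustive, exclusive and monotone", {
  withr::local_seed(99)
  cz <- stats::runif(1e4, 0, 80)
  cl <- stats::runif(1e4, 0, 80)
  dec <- classify_oza(cz, cl)
  expect_false(anyNA(dec$label))                 # exactly one label each
  expect_identical(nrow(dec), 10000L)
  # growing both distances never moves pterional_sufficient -> oza_recommended
  bigger <- classify_oza(cz + stats::runif(1e4, 0, 40),
                         cl + stats::runif(1e4, 0, 40))
  worsened <- dec$label == "pterional_sufficient" & bigger$label == "oza_recommended"
  expect_false(any(worsened))
})

test_that("Pearson r and p match the covariance-formula oracle", {
  withr::local_seed(5)
  co <- tibble::tibble(
    height_A_mm = stats::rnorm(40, 4.9, 3.8),
    height_B_mm = stats::rnorm(40, 5.7, 3.1),
    width_B_mm = stats::rnorm(40, 15.7, 3.4)
  )
  co$cz_mm <- abs(30 - 2 * co$height_A_mm + stats::rnorm(40, 0, 5))
  co$cl_mm <- abs(30 + co$height_B_mm + stats::rnorm(40, 0, 5))
  rep <- tidy(pearson_with_bonferroni(co))
  cols <- c(cz = "cz_mm", cl = "cl_mm", height_A = "height_A_mm",
            height_B = "height_B_mm", width_B = "width_B_mm")
  for (i in seq_len(nrow(rep))) {
    o <- pearson_oracle(co[[cols[rep$outcome[i]]]], co[[cols[rep$predictor[i]]]])
    expect_equal(rep$r[i], o$r, tolerance = 1e-12)
    expect_equal(rep$p[i], o$p, tolerance = 1e-12)
  }
})

test_that("a perfectly linear pair gives r = 1", {
  withr::local_seed(6)
  co <- tibble::tibble(
    height_A_mm = stats::rnorm(20), width_B_mm = stats::rnorm(20),
    cl_mm = abs(stats::rnorm(20))
  )
  co$height_B_mm <- stats::rnorm(20)
  co$cz_mm <- 2 * co$height_B_mm
  rep <- tidy(pearson_with_bonferroni(co))
  r <- rep$r[rep$outcome == "cz" & rep$predictor == "height_B"]
  expect_equal(r, 1, tolerance = 1e-12)
})

test_that("Bonferroni correction gives the conventional 0.017 threshold", {
  withr::local_seed(7)
  co <- tibble::tibble(
    height_A_mm = stats::rnorm(10), height_B_mm = stats::rnorm(10),
    width_B_mm = stats::rnorm(10), cz_mm = abs(stats::rnorm(10)),
    cl_mm = abs(stats::rnorm(10))
  )
  rep <- pearson_with_bonferroni(co)
  expect_equal(rep$corrected_alpha, 0.05 / 3)
  expect_identical(sprintf("%.3f", rep$corrected_alpha), "0.017")
  # corrected-significant pairs are a subset of family-alpha-significant ones
  tab <- tidy(rep)
  expect_true(all(tab$p[tab$significant] < 0.05))
})

test_that("degenerate cohorts are rejected with named diagnostics", {
  co <- tibble::tibble(
    height_A_mm = c(1, 2, 3), height_B_mm = c(2, 2, 2),
    width_B_mm = c(1, 3, 2), cz_mm = c(1, 2, 4), cl_mm = c(2, 1, 5)
  )
  expect_error(pearson_with_bonferroni(co), "height_B_mm")
  expect_error(pearson_with_bonferroni(co[1:2, ]), "at least 3")
  expect_error(pearson_with_bonferroni(dplyr::select(co, -cz_mm)), "cz_mm")
})

test_that("glance summarises the correlation family", {
  withr::local_seed(9)
  co <- simulate_cohort(cohort_params(n = 10), small_skull, seed = 2)
  rep <- pearson_with_bonferroni(co)
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  expect_identical(g$n, 10L)
  expect_equal(g$corrected_alpha, 0.05 / 3)
  expect_true(g$n_significant <= 6)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("cohort summaries use the sample SD and format conventionally", {
  co <- tibble::tibble(subject_id = 1:3, height_A_mm = c(1, 2, 3))
  s <- summarize_cohort(co)
  expect_identical(nrow(s), 1L)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)      # n - 1 denominator
  expect_equal(c(s$min, s$max), c(1, 3))
  expect_match(s$formatted, "2.0 ± 1.0")
  single <- summarize_cohort(tibble::tibble(height_A_mm = 4.2))
  expect_equal(single$sd, 0)
  expect_equal(single$min, single$max)
  expect_error(summarize_cohort(tibble::tibble(height_A_mm = numeric())), "empty")
})
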