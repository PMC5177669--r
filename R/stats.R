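#' Orbitozygomatic-approach decision rule
#'
#' Classifies each (C-Z, C-L) distance pair: when both distances are
#' below `low_mm` (default 30 mm, i.e. 3 cm) point C sits close to both
#' the zygomatic arch and the lateral canthus and the orbitozygomatic
#' extension is recommended; when both exceed `high_mm` (default 40 mm, 4
#' cm) a standard pterional craniotomy should suffice; anything else —
#' including values exactly on a threshold — is indeterminate and needs
#' individual review.
#'
#' @param cz_mm,cl_mm Numeric vectors of non-negative distances, mm
#'   (recycled to a common length).
#' @param low_mm,high_mm Decision thresholds, mm; `low_mm < high_mm`.
#' @return A tibble with `cz_mm`, `cl_mm`, `label` (factor with levels
#'   `oza_recommended`, `indeterminate`, `pterional_sufficient`),
#'   `low_mm`, `high_mm`.
#' @export
classify_oza <- function(cz_mm, cl_mm, low_mm = 30, high_mm = 40) {
  if (any(!is.finite(cz_mm)) || any(!is.finite(cl_mm)) ||
      any(cz_mm < 0) || any(cl_mm < 0)) {
    stop("distances must be finite and non-negative (mm)", call. = FALSE)
  }
  if (!(low_mm < high_mm)) stop("low_mm must be < high_mm", call. = FALSE)
  n <- max(length(cz_mm), length(cl_mm))
  cz <- rep_len(cz_mm, n)
  cl <- rep_len(cl_mm, n)
  label <- dplyr::case_when(
    cz < low_mm & cl < low_mm ~ "oza_recommended",
    cz > high_mm & cl > high_mm ~ "pterional_sufficient",
    TRUE ~ "indeterminate"
  )
  tibble::tibble(
    cz_mm = cz, cl_mm = cl,
    label = factor(label, levels = c("oza_recommended", "indeterminate",
                                     "pterional_sufficient")),
    low_mm = low_mm, high_mm = high_mm
  )
}

#' Append the approach decision to a cohort table
#'
#' @param cohort A cohort tibble with `cz_mm` and `cl_mm` columns.
#' @param low_mm,high_mm Thresholds passed to [classify_oza()].
#' @return The cohort with an added `approach` factor column.
#' @export
add_oza_decision <- function(cohort, low_mm = 30, high_mm = 40) {
  dec <- classify_oza(cohort$cz_mm, cohort$cl_mm, low_mm, high_mm)
  dplyr::mutate(cohort, approach = dec$label)
}

#' Pearson correlations of the C distances with Bonferroni correction
#'
#' For each outcome distance (C-Z, C-L) against each anatomical predictor
#' (height of A, height of B, width of B), computes the Pearson
#' correlation coefficient and its two-sided p-value from the t
#' distribution with `n - 2` degrees of freedom, then flags significance
#' at the Bonferroni-corrected level `family_alpha / m` (default 0.05 / 3
#' = 0.0167, conventionally reported as 0.017).
#'
#' @param cohort A cohort tibble with the measurement columns.
#' @param family_alpha Family-wise significance level.
#' @param m Number of comparisons per outcome family.
#' @return An object of class `oza_correlation` wrapping the per-pair
#'   tibble; use [generics::tidy()] / [generics::glance()] to extract it.
#' @export
pearson_with_bonferroni <- function(cohort, family_alpha = 0.05, m = 3) {
  outcomes <- c(cz = "cz_mm", cl = "cl_mm")
  predictors <- c(height_A = "height_A_mm", height_B = "height_B_mm",
                  width_B = "width_B_mm")
  needed <- c(outcomes, predictors)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(cohort[needed])) stop("cohort has missing values", call. = FALSE)
  n <- nrow(cohort)
  if (n < 3) stop("need at least 3 samples for a correlation test", call. = FALSE)
  for (col in needed) {
    if (stats::sd(cohort[[col]]) == 0) {
      stop("correlation undefined: column '", col, "' has zero variance",
           call. = FALSE)
    }
  }
  corrected_alpha <- family_alpha / m
  grid <- tidyr::expand_grid(outcome = names(outcomes),
                             predictor = names(predictors))
  tab <- purrr::pmap_dfr(grid, function(outcome, predictor) {
    ct <- stats::cor.test(cohort[[outcomes[[outcome]]]],
                          cohort[[predictors[[predictor]]]],
                          method = "pearson", alternative = "two.sided")
    tibble::tibble(
      outcome = outcome, predictor = predictor,
      r = unname(ct$estimate), p = ct$p.value,
      significant = ct$p.value < corrected_alpha
    )
  })
  structure(list(table = tab, n = n, family_alpha = family_alpha, m = m,
                 corrected_alpha = corrected_alpha),
            class = "oza_correlation")
}

#' @export
print.oza_correlation <- function(x, ...) {
  cat(sprintf(
    "Pearson correlation report (n = %d, corrected alpha = %.3f)\n",
    x$n, x$corrected_alpha
  ))
  print(x$table, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correlation report
#'
#' @param x An `oza_correlation` object.
#' @param ... Unused.
#' @return A tibble with one row per (outcome, predictor) pair: `r`, `p`,
#'   `significant`, `corrected_alpha`, `n`.
#' @exportS3Method generics::tidy
tidy.oza_correlation <- function(x, ...) {
  dplyr::mutate(x$table, corrected_alpha = x$corrected_alpha, n = x$n)
}

#' Glance at a correlation report
#'
#' @param x An `oza_correlation` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `family_alpha`, `m`, `corrected_alpha`,
#'   `n_significant`.
#' @exportS3Method generics::glance
glance.oza_correlation <- function(x, ...) {
  tibble::tibble(
    n = x$n, family_alpha = x$family_alpha, m = x$m,
    corrected_alpha = x$corrected_alpha,
    n_significant = sum(x$table$significant)
  )
}

#' Cohort summary statistics
#'
#' Mean, sample SD (n - 1 denominator), range and count for each
#' measured quantity, with the conventional `"mean +/- sd (min-max)"`
#' formatting.
#'
#' @param cohort A cohort tibble (numeric measurement columns are
#'   summarised; `subject_id` is ignored).
#' @return A tibble with one row per quantity: `quantity`, `mean`, `sd`,
#'   `min`, `max`, `n`, `formatted`.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) < 1) stop("cohort is empty", call. = FALSE)
  num <- dplyr::select(cohort, dplyr::where(is.numeric), -dplyr::any_of("subject_id"))
  tidyr::pivot_longer(num, dplyr::everything(),
                      names_to = "quantity", values_to = "value") |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      min = min(.data$value),
      max = max(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(formatted = sprintf("%.1f ± %.1f (%.1f–%.1f)",
                                      .data$mean, .data$sd, .data$min, .data$max))
}
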