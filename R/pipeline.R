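#' Pipeline run configuration
#'
#' Validated, nested configuration for [run_pipeline()]. Unknown keys in
#' any section are rejected, so a typo cannot silently fall back to a
#' default.
#'
#' @param skull A [skull_params()] record or argument list.
#' @param cohort A [cohort_params()] record or argument list.
#' @param thresholds List with `low_mm`, `high_mm` decision thresholds.
#' @param statistics List with `family_alpha`, `m`.
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory.
#' @param cz_mode `"polyline"` or `"midpoint"` (see [measure_all()]).
#' @param write_plot Write the point-C scatter PNG (excluded from the
#'   bit-exact reproducibility contract, which covers numeric outputs).
#' @return A list of class `run_config`.
#' @export
run_config <- function(skull = skull_params(), cohort = cohort_params(),
                       thresholds = list(low_mm = 30, high_mm = 40),
                       statistics = list(family_alpha = 0.05, m = 3),
                       seed = 7L, out_dir = tempfile("ozaplan_run_"),
                       cz_mode = "polyline", write_plot = TRUE) {
  if (!inherits(skull, "skull_params")) skull <- do.call(skull_params, skull)
  if (!inherits(cohort, "cohort_params")) cohort <- do.call(cohort_params, cohort)
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(thresholds, c("low_mm", "high_mm"), "thresholds")
  check_keys(statistics, c("family_alpha", "m"), "statistics")
  if (!(thresholds$low_mm < thresholds$high_mm)) {
    stop("thresholds: low_mm must be < high_mm", call. = FALSE)
  }
  structure(list(
    skull = skull, cohort = cohort, thresholds = thresholds,
    statistics = statistics, seed = as.integer(seed), out_dir = out_dir,
    cz_mode = match.arg(cz_mode, c("polyline", "midpoint")),
    write_plot = isTRUE(write_plot)
  ), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Generate skull -> sample vessels -> project trajectories -> measure ->
#' classify -> correlate -> summarise, writing every artifact (cohort
#' CSV, decisions CSV, correlation CSV, summary CSV, scatter PNG, and a
#' JSON run manifest capturing config, seed and package version) to
#' `config$out_dir`. Re-running from the written manifest reproduces all
#' numeric outputs bit-exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the result tibbles and the file paths.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[ozaplan] %s (%.1fs)", msg,
                                         as.numeric(Sys.time() - t0, "secs")))
  stage(sprintf("seed %d: generating skull phantom", config$seed))
  anatomy <- generate_skull(config$skull, seed = config$seed)
  stage(sprintf("simulating cohort (n = %d)", config$cohort$n))
  cohort <- simulate_cohort(config$cohort, anatomy, seed = config$seed,
                            cz_mode = config$cz_mode)
  stage("classifying approach need")
  decisions <- add_oza_decision(cohort, config$thresholds$low_mm,
                                config$thresholds$high_mm)
  stage("correlation analysis")
  correlations <- if (nrow(cohort) >= 3) {
    tidy(pearson_with_bonferroni(cohort, config$statistics$family_alpha,
                                 config$statistics$m))
  } else {
    warning("correlation stage: n - 2 = ", nrow(cohort) - 2,
            " degrees of freedom; p-values skipped", call. = FALSE)
    outs <- c(cz = "cz_mm", cl = "cl_mm")
    preds <- c(height_A = "height_A_mm", height_B = "height_B_mm",
               width_B = "width_B_mm")
    purrr::pmap_dfr(
      tidyr::expand_grid(outcome = names(outs), predictor = names(preds)),
      function(outcome, predictor) {
        tibble::tibble(
          outcome = outcome, predictor = predictor,
          r = stats::cor(cohort[[outs[[outcome]]]], cohort[[preds[[predictor]]]]),
          p = NA_real_, significant = NA,
          corrected_alpha = config$statistics$family_alpha / config$statistics$m,
          n = nrow(cohort)
        )
      }
    )
  }
  summary_stats <- summarize_cohort(cohort)
  paths <- list(
    cohort = file.path(config$out_dir, "cohort.csv"),
    decisions = file.path(config$out_dir, "decisions.csv"),
    correlations = file.path(config$out_dir, "correlations.csv"),
    summary = file.path(config$out_dir, "summary.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_cohort_csv(cohort, paths$cohort)
  readr::write_csv(decisions, paths$decisions)
  readr::write_csv(correlations, paths$correlations)
  readr::write_csv(summary_stats, paths$summary)
  if (config$write_plot) {
    paths$scatter <- file.path(config$out_dir, "point_c_scatter.png")
    p <- plot_point_c(decisions)
    grDevices::png(paths$scatter, width = 1200, height = 900, res = 150)
    print(p)
    grDevices::dev.off()
  }
  write_run_manifest(config, paths$manifest)
  stage("done")
  invisible(list(anatomy = anatomy, cohort = cohort, decisions = decisions,
                 correlations = correlations, summary = summary_stats,
                 paths = paths, config = config))
}

#' Write / read a run manifest
#'
#' The manifest is a JSON record of everything needed to reproduce a run:
#' the full configuration, the seed and the package version.
#'
#' @param config A [run_config()].
#' @param path Manifest path.
#' @return `write_run_manifest()` returns `path` invisibly;
#'   `read_run_manifest()` returns a [run_config()] (the recorded
#'   `out_dir` is preserved unless overridden via `out_dir`).
#' @export
write_run_manifest <- function(config, path) {
  manifest <- list(
    package = "ozaplan",
    version = as.character(utils::packageVersion("ozaplan")),
    seed = config$seed,
    skull = unclass(config$skull),
    cohort = unclass(config$cohort),
    thresholds = config$thresholds,
    statistics = config$statistics,
    cz_mode = config$cz_mode,
    out_dir = config$out_dir
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_manifest
#' @param out_dir Optional replacement output directory on read.
#' @export
read_run_manifest <- function(path, out_dir = NULL) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    skull = skull_params(m$skull$semi_axes, m$skull$center_height,
                         m$skull$subdivisions),
    cohort = cohort_params(m$cohort$n, unlist(m$cohort$height_A),
                           unlist(m$cohort$height_B), unlist(m$cohort$width_B),
                           m$cohort$a_posterior_offset,
                           m$cohort$b_anterior_offset,
                           m$cohort$jitter_sd, m$cohort$mirror_sides),
    thresholds = m$thresholds,
    statistics = m$statistics,
    seed = m$seed,
    out_dir = out_dir %||% m$out_dir,
    cz_mode = m$cz_mode
  )
}

#' Export landmarks and vessels as JSON
#'
#' Writes the landmark set (and vascular points, if sampled) with
#' explicit unit and frame fields so external tools can interpret the
#' coordinates.
#'
#' @param anatomy An [generate_skull()] model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(anatomy, path) {
  lm <- anatomy$landmarks
  out <- list(
    unit = "mm",
    frame = list(origin = "dorsum sellae apex",
                 axes = "+x lateral, +y anterior, +z superior",
                 midsagittal_plane = "x = 0"),
    landmarks = list(
      dorsum_sellae = lm$dorsum_sellae,
      eac = lm$eac,
      lateral_canthus = lm$lateral_canthus,
      zygomatic_arch = lapply(lm$zygomatic_arch, function(m)
        unname(apply(rbind(m), 1, as.numeric, simplify = FALSE))),
      midsagittal_normal = lm$midsagittal_normal
    ),
    vessels = anatomy$vessels
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
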