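#' Load the packaged five-patient measurement table
#'
#' The per-patient craniometric measurements of the five surgically
#' treated basilar apex aneurysm patients, packaged as a plain-text
#' fixture (`inst/extdata/table2_patients.csv`). The file header
#' documents how ambiguous printed cells were transcribed. The loader
#' validates the record count, the measurement invariants and a numeric
#' checksum before returning.
#'
#' @return A tibble with 5 rows: `patient`, `age`, `sex`, `location`,
#'   `size_mm`, `ruptured`, `height_A_mm`, `height_B_mm`, `width_B_mm`,
#'   `cz_mm`, `cl_mm`, `approach`.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_patients.csv", package = "ozaplan",
                      mustWork = TRUE)
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           patient = readr::col_integer(),
                           age = readr::col_integer(),
                           sex = readr::col_character(),
                           location = readr::col_character(),
                           ruptured = readr::col_character(),
                           approach = readr::col_character(),
                           .default = readr::col_double()
                         ))
  if (nrow(tab) != 5) {
    stop("packaging error: fixture must contain exactly 5 records", call. = FALSE)
  }
  if (any(tab$height_A_mm < 3 | tab$height_A_mm > 12)) {
    stop("packaging error: heights of A must lie in [3, 12] mm", call. = FALSE)
  }
  if (any(tab$cz_mm < 0 | tab$cl_mm < 0)) {
    stop("packaging error: C-Z / C-L distances must be non-negative", call. = FALSE)
  }
  checksum <- sum(tab$patient, tab$age, tab$size_mm, tab$height_A_mm,
                  tab$height_B_mm, tab$width_B_mm, tab$cz_mm, tab$cl_mm)
  if (abs(checksum - 950.8) > 1e-6) {
    stop("packaging error: fixture checksum mismatch", call. = FALSE)
  }
  tab
}
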