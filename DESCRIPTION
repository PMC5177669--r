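Package: ozaplan
Title: Virtual Trajectory Planning for Basilar Apex Aneurysm Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based craniometric analysis of the surgical
    corridor to basilar apex aneurysms. Constructs the virtual trajectory from
    the basilar apex through the internal carotid artery bifurcation, projects
    it onto the cranial surface to obtain the cranial window centre (point C),
    measures the distances from point C to the zygomatic arch and lateral
    canthus, and applies a distance-based decision rule for the
    orbitozygomatic approach. Includes a parametric synthetic-anatomy
    generator calibrated to published cohort statistics, a voxel phantom
    path, Pearson correlation reporting with Bonferroni correction, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
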