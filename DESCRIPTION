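Package: tessfundus
Title: Objective Quantification of Fundus Tessellation from Color Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes tessellated fundus indices (TFI-1, TFI-2, TFI-3) from the
    red, green and blue channel statistics of a circular region placed between
    the fovea and the optic disc of a color fundus photograph, and provides the
    accompanying cohort statistics: Spearman rank correlation with choroidal
    thickness and axial length, Steel-Dwass all-pairs nonparametric comparison
    across tessellation grades, Fleiss kappa for inter-rater agreement, and the
    two-way absolute-agreement intraclass correlation for intersession
    repeatability. A synthetic-cohort module renders fundus-like images whose
    tessellation visibility is a monotone function of simulated choroidal
    thickness, so the whole pipeline can be exercised end to end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    jpeg,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
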