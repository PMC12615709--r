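Package: stainqual
Title: Quantitative Image-Quality Evaluation of Microbial Stains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative comparison of microbiological staining
    protocols from brightfield micrographs. Implements five no-reference image
    quality metrics (Laplacian-variance sharpness, Shannon entropy of the
    intensity histogram, global contrast, signal-to-noise ratio, and normalized
    Sobel edge intensity), Hough-transform detection and binary masking of
    microscope-embedded marker lines, exact small-sample Wilcoxon signed-rank
    tests with paired Cohen's d effect sizes, a seeded synthetic stained-smear
    generator for validation, and a manifest-driven pipeline that turns paired
    test-dye/standard-dye micrographs into per-image metric tables and
    per-metric statistical summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
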