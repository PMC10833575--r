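Package: fluorquant
Title: Standardized Quantification of Fluorescent Dye Performance in
    Resected Tumor Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic, standardized quantification of near-infrared
    fluorescence in bread-loafed surgical specimens. Builds signal and
    background regions of interest from tumor and bread-loaf delineations
    by millimeter-parameterized Euclidean dilation, computes mean
    fluorescence intensities via fixed-bin histograms, and derives
    signal-to-background ratios (SBR, non-targeted dyes such as ICG) and
    tumor-to-background ratios (TBR, targeted dyes such as SGM-101).
    Includes an observer-agreement harness (Dice similarity coefficient
    schedules and two-way absolute-agreement intraclass correlation with
    F-based confidence intervals), and a synthetic phantom generator with
    analytic ground truth for validating the full workflow without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
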