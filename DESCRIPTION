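Package: tomonodule
Title: Simulated Pulmonary Nodules and Dose Reduction in Chest Tomosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation pipeline for studying manual size measurements of
    pulmonary nodules in digital chest tomosynthesis at reduced radiation
    dose. Generates ellipsoid nodule populations with controlled
    volume-equivalent diameter and axis ratio, inserts them into raw
    projection radiographs by analytic ray tracing with detector blur,
    patient-motion shifts and scatter contrast correction, simulates
    acquisition at lower dose by adding noise-power-spectrum shaped and
    DQE-corrected noise, reconstructs coronal sections by filtered
    shift-and-add back-projection, emulates repeated diameter measurements
    with a stochastic observer model, and computes the accuracy and
    precision statistics of the measurements (bias, intra-, inter- and
    internodule variability with small-sample correction, repeated-measures
    ANOVA with Bonferroni post hoc tests, and Kendall rank correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
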