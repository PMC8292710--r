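Package: ventavoid
Title: Functional Lung Avoidance Proton Planning with 4DCT Ventilation Imaging
Version: 0.1.0
Authors@R: person("ventavoid", "maintainers", email = "maintainers@ventavoid.org", role = c("aut", "cre"))
Description: End-to-end research pipeline for ventilation-guided functional
    lung avoidance in scanned proton therapy. Generates a deformable 4DCT
    lung phantom with tissue-conserving motion and analytically known
    ventilation, estimates exhale-to-inhale correspondence by deformable
    image registration, computes Hounsfield-unit based fractional
    ventilation images and regional ventilation profiles, derives
    functional-lung and planning structures, builds a simplified
    scenario-aware proton pencil-beam dose model, robustly optimizes spot
    weights with and without functional-lung avoidance objectives, simulates
    4D dynamic delivery to quantify the motion interplay effect, and reports
    dose-volume, conformity and normal-tissue complication probability
    (NTCP) metrics with the accompanying statistical comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
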