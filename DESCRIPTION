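Package: ebbench
Title: Bench Simulation and Accuracy Analysis of Esophageal Balloon Catheters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of a pressure-controlled bench model for
    esophageal balloon (EB) catheters (balloon mounted in an ex-vivo esophagus
    inside a pressure chamber), together with the analysis layers used to
    characterize catheter performance: transesophageal pressure (TEP) accuracy
    banding and accuracy-volume ranges, balloon elastance and residual-volume
    estimation from pressure-volume curves, occlusion-test transmission-ratio
    volume titration, and nonparametric group statistics with Bonferroni
    post-hoc comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
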