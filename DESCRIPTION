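Package: axocycle
Title: Cell-Cycle Kinetics, Division Orientation and nCounter Expression
    Analysis for Regenerating Spinal Cord
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for studies of neural stem cell
    behaviour in the regenerating axolotl spinal cord. Implements a
    cumulative BrdU/EdU labeling model with division-mode-dependent growth
    correction and weighted least-squares fitting with parabolic confidence
    intervals; mitotic-index estimation from sectioned tissue with
    finite-population error correction; mitotic-spindle orientation
    statistics with a uniformity test and cleavage-plane angle analysis;
    and a NanoString nCounter normalization, negative-binomial differential
    expression and cross-dataset concordance pipeline. An agent-based
    cell-population simulator and count/coordinate generators provide
    ground-truth synthetic data for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
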