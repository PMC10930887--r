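Package: ansia
Title: Quantification of Stromal Invasion Fronts, Invasive Forks, Cell
    Motility and Gene-Set Module Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for nanopatterned stromal invasion assays in
    which a fluorescently labeled epithelial monolayer advances into a
    stromal compartment along a quasi-one-dimensional axis. Converts
    time-lapse image stacks or traced region-of-interest polygons into
    one-dimensional invasion-front profiles, computes the normalized
    extent of invasion (change in invaded area divided by the initial
    interface length), detects invasive forks on moving-average-smoothed
    profiles with a side-window peak rule, and summarizes fork-depth
    distributions. Also computes per-cell motility metrics (displacement,
    velocity, directionality) from trajectory tables and per-cell gene-set
    module scores (mean z-scaled expression) with Pearson correlations
    between scores. Ships synthetic-data generators with machine-readable
    ground truth for invasion stacks, correlated-random-walk trajectories,
    and expression matrices with planted module correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    EBImage,
    Matrix,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
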