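Package: leafseal
Title: Self-Sealing Kinematics, Morphometry and Biomechanics of Succulent Leaves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the rapid self-sealing movement of succulent
    Delosperma leaves after a circumferential (ring) incision. Provides seeded
    simulation of marker-tracked leaf contraction experiments, segment-wise
    absolute and relative contraction from marker trajectories (direct marker
    spacing for straight leaves, polynomial mid-line fits with arc-length
    analysis for recurved leaves), rank-based factorial statistics
    (Scheirer-Ray-Hare tests with Bonferroni-adjusted pairwise Wilcoxon
    post-hoc comparisons), cross-section morphometry of the five concentric
    leaf tissue layers, and extraction of tissue mechanical properties from
    tensile-test traces including a calibrated turgor-based parenchyma
    modulus. A reproducible pipeline assembles the stages into run
    directories with full provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
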