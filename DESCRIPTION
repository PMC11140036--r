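Package: polarcell
Title: Automated Planar Cell Polarity Angle Measurement and Cell Counting
    from Binary Micrographs
Version: 0.1.0
Authors@R: person("polarcell", "authors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Counts cells ("chunks" of white pixels) in binary micrograph
    masks and measures each cell's planar polarity angle as the direction
    from the chunk centroid to the centroid of a directional inclusion of
    black pixels (a "cave", e.g. the unlabeled fonticulus of a hair cell).
    Open concavities such as U- or V-shaped stereocilia bundles can be
    enclosed with a convex-hull "plastic wrap" bridging step. Provides size,
    border and doublet handling, Fisher circular descriptive statistics,
    rose diagrams, annotated overlay images, batch processing, a synthetic
    ground-truth fixture generator, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    optparse,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
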