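Package: signedclust
Title: Signed Clustering Coefficients for Weighted Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Local and global clustering coefficients for signed weighted
    networks, in particular networks built from correlation matrices.
    Implements the classical unsigned indices of Watts-Strogatz, Onnela and
    Zhang-Horvath together with signed generalizations in which triangles
    with a negative edge-sign product contribute negatively, plus a global
    signed coefficient.  Includes a ring-lattice simulation framework for
    studying the convergence of signed and unsigned indices as the
    proportion of negative triangles grows, and a correlation-network
    analysis pipeline (reverse scoring, edge and triangle censuses,
    index-agreement tables, threshold sweeps) with a synthetic
    factor-model generator emulating multi-factor questionnaire data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
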