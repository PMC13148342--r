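Package: ousiometrics
Title: Essential-Meaning Frameworks, Ousiograms, and an Ousiometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ousiometrics, the quantitative study of the essential
    meaning carried by words. Reads and centers valence-arousal-dominance
    (VAD) lexicons scored on [0,1] best-worst scales, derives the orthogonal
    goodness-aggression-structure (GAS) basis by singular value decomposition
    with fixed sign conventions, rotates its primary plane by -pi/4 into the
    power-danger-structure (PDS) basis, and transforms word scores between
    frameworks. Builds annotated weighted 2D histograms ("ousiograms") with
    marginals, weighted medians, SVD ellipses, convex-hull boundary labels
    and internal ray labels; computes token-weighted corpus statistics
    through a lexical lens, including the safety-bias summary; and provides
    an "ousiometer" that scores plain text over sliding windows to produce
    essential-meaning time series and power-danger trajectories. Includes
    deterministic synthetic lexicon and corpus generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    patchwork,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    stringi,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
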