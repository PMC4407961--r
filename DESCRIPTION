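Package: nichepair
Title: Trait-Based Tests of Environmental Filtering and Competition in
    Coexisting Species Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether pairs of species coexisting in an extreme habitat
    are more similar (environmental filtering) or more different (competition
    and character displacement) in functional morphology than expected from
    their regional species pool, and asks whether that pattern was already
    present in their inferred ancestors.  Morphometric measurements are
    allometrically standardized against body length; observed pairwise
    Euclidean trait distances are compared with a null distribution obtained
    by simulating virtual species uniformly within the trait ranges of the
    regional pool; ancestral trait values at the most recent common ancestor
    of each focal species and its sister lineage are reconstructed under
    Brownian-motion and Ornstein-Uhlenbeck models fitted by maximum
    likelihood and selected by AIC.  Includes a synthetic-data generator
    (pure-birth trees, trait evolution, planted focal pairs) so the whole
    pipeline is testable without field data, and a small command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
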