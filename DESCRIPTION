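Package: museumdiv
Title: Species Delimitation, Historical Biogeography and Diversification
    Dynamics for Dated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-tree-inference pipeline for testing 'museum' versus 'cradle'
    models of tropical diversification. Provides mean-path-length (MPL)
    ultrametricization of non-clocklike gene trees with a per-node molecular
    clock test, single-threshold General Mixed Yule Coalescent (GMYC) species
    delimitation with IUPAC consensus reduction of cluster sequences,
    time-stratified Dispersal-Extinction-Cladogenesis (DEC) ancestral-range
    estimation over paleogeographically scaled dispersal matrices, and a
    diversification-rate battery: the gamma statistic and MCCR test under
    incomplete sampling, rate-constant versus rate-variable model selection by
    AIC, fixed-time rate-shift tests, the relative cladogenesis test, and
    Magallon-Sanderson net diversification estimators. Seeded generators
    simulate every input with ground truth for calibration and recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    phangorn,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
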