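Package: reactraj
Title: Reaction-Event Mining in Catalyst Exploration Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated reactivity analysis of organometallic
    catalyst libraries. Generates combinatorial complex libraries
    (scaffold x substituent x adduct), perceives bonds from 3D geometry,
    identifies unique conformers along multi-frame XYZ trajectories by
    labeled graph isomorphism, extracts formed/broken bond events relative
    to a reference structure, and mines the resulting reactivity database
    with energy-window filters, feature-correlation histograms and k-modes
    clustering of categorical reaction labels. A deterministic synthetic
    fixture generator scripts bond events into toy trajectories so the
    full pipeline is testable without electronic-structure calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
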