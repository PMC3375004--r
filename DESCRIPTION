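Package: micromr
Title: Molecular Replacement and Density-Guided Model Rebuilding at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained, desk-scale implementation of the molecular
    replacement and iterative model-rebuilding workflow for macromolecular
    crystallography: template preparation from a target/template sequence
    alignment, rigid-body placement of search models against observed
    structure-factor amplitudes by a correlation-scored rotation/translation
    search, solvent flattening and non-crystallographic-symmetry map
    averaging, density-guided Monte Carlo fragment rebuilding with a combined
    geometry-plus-density score, real-space refinement, and a
    convergence-controlled autobuild loop.  A synthetic-crystal module
    generates toy polyalanine/helical targets, perturbed homolog templates and
    simulated amplitudes so the whole pipeline is verifiable offline,
    end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
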