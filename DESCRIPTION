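Package: bxs
Title: Standardized Tractography and Common Connectivity Spaces for Diverse Brains
Version: 0.1.0
Authors@R: person("bxs", "maintainers", email = "bxs@example.org", role = c("aut", "cre"))
Description: Protocol-constrained probabilistic streamline tractography,
    population white-matter tract atlases, cortical connectivity blueprints,
    symmetric Kullback-Leibler divergence mapping between brains (dense,
    parcellated, joint ontogeny-phylogeny), spectral-embedding atlas
    translation, and tract-maturation statistics.  All analyses run
    end-to-end on built-in synthetic phantoms with known ground truth, so
    the full pipeline is testable without any imaging data download.
    Includes minimal readers and writers for NIfTI-1 volumes, GIFTI
    surfaces/metrics/labels, JSON tract-protocol manifests and TSV label
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
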