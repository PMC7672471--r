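Package: exoalign
Title: Alignment and Crosslink Deconvolution of Strand-Separated ChIP-exo Profiles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns multi-experiment, strand-separated ChIP-exo/ChIP-nexus tag
    profiles across coordinately bound genomic regions using an affine-gap
    overlap extension of Needleman-Wunsch dynamic programming and progressive
    profile merging, then deconvolves the aligned composite into individual
    protein-DNA crosslinking events with an EM mixture model under a
    sparseness-promoting negative Dirichlet prior. Produces per-experiment
    crosslinking-strength matrices, cross-condition fold-difference tables,
    and a PCA summary of protein spatial organization. Includes a synthetic
    ChIP-exo data generator with known alignment and crosslinking truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
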