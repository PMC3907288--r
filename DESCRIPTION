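Package: domtrace
Title: Phylogenomic Tracing of Protein Domain Gain and Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Census-based phylogenomics of protein domain fold families (FFs)
    across the three superkingdoms of life. Builds abundance and occurrence
    character matrices from per-proteome SCOP fold-family assignment tables,
    recodes them into ordered multistate characters, reconstructs trees of
    life and trees of domains by Wagner (ordered) parsimony with Lundberg
    rooting, traces per-branch domain gain and loss events, derives relative
    (node-distance) and geological age timelines of fold families, computes
    distribution and persistence statistics, and compares tree topologies by
    nodal root-mean-square deviation with a guided randomization test. A
    birth-duplication-loss simulator generates assignment tables with known
    evolutionary histories so every pipeline stage can be validated against
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'census-io.R'
    'domtrace-package.R'
    'gainloss.R'
    'matrix-io.R'
    'parsimony.R'
    'pipeline.R'
    'sankoff-engine.R'
    'simulate.R'
    'timeline.R'
    'treecmp.R'
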