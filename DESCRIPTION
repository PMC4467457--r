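Package: sifted
Title: Quantitative TALE-DNA Binding Specificity Inference and Off-Target
    Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers per-repeat binding free-energy changes (ddG) of
    transcription activator-like effector (TALE) proteins from custom
    protein-binding microarray (PBM) intensities under a Boltzmann
    occupancy model, fits a context-aware regularized regression (SIFTED)
    that predicts the energy matrix and position weight matrix of an
    arbitrary TALE from its RVD sequence, and enumerates, scans and ranks
    potential genomic off-target binding sites under a relative-Kd bound.
    Includes a synthetic-data generator that emulates the probe designs
    and noise structure of the PBM experiments so the whole stack can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    glmnet,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: MotifDiscovery, Regression, Bayesian, Transcription
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'tale-protein.R'
    'energy-matrix.R'
    'probe-design.R'
    'pbm-quantify.R'
    'ddg-inference.R'
    'sifted-model.R'
    'offtarget-scan.R'
    'synthetic-data.R'
    'sifted-package.R'
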