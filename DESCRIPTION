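Package: degronScan
Title: Tiled-Peptidome Stability Screens and Degron Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for pooled tiled-peptidome protein
    stability screens read out by four-bin fluorescence-activated cell
    sorting and deep sequencing. Designs 51-nt / 17-residue tiled oligo
    libraries from coding sequences, quantifies library members across
    FACS bins with single-mismatch read matching, computes the Protein
    Stability Index (PSI) per peptide and per residue, trains a
    ridge-regularized logistic-regression degron predictor on amino-acid
    composition, scans proteomes for degron probability, and
    characterizes called degrons by hydropathy, secondary structure and
    solvent accessibility. Includes a synthetic-screen simulator with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
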