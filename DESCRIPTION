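Package: pepbind
Title: Template-Based Prediction of Protein-Peptide Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts where on a protein structure a given peptide is most
    likely to bind. Given a receptor structure and a peptide sequence, the
    pipeline superposes the receptor onto every chain of an interaction
    template library with a TM-score based structural alignment, transfers
    template interface residues onto the receptor, scores each transferred
    surface with a random forest trained on alignment-, composition-,
    secondary-structure- and surface-derived features, clusters the surfaces
    by spatial overlap, and reports per-residue binding-site probabilities
    together with a calibrated global confidence score. Includes tools to
    build template libraries from directories of PDB files, a benchmark
    harness with dataset filters and evaluation criteria, a template-coverage
    regression analysis, and a deterministic synthetic-structure generator so
    the whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    jsonlite,
    bio3d,
    Biostrings,
    MASS,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
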