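Package: fadsite
Title: Prediction of FAD-Binding Residues from PSSM Profiles and
    Significant Amino Acid Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Residue-level prediction of flavin adenine dinucleotide (FAD)
    binding sites in proteins, with an emphasis on electron transport
    chain flavoproteins. Sequence windows centred on each residue are
    encoded as one-hot, PAM250, BLOSUM62 or sigmoid-normalised PSSM
    feature vectors; features are optionally augmented by F-score ranking
    and by significant amino acid pairs (SAAPs) selected with a
    hypergeometric enrichment statistic. Classification uses a radial
    basis function network with Gaussian kernels centred on all training
    windows and least-squares output weights. Includes a full evaluation
    harness (confusion-matrix metrics, Matthews correlation coefficient,
    ROC/AUC, stratified k-fold cross-validation, leave-one-protein-out),
    an amino-acid composition analysis, a seeded synthetic-data generator
    with planted signal, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
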