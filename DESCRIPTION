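Package: ppmfold
Title: Performance and Generalizability of De Novo RNA Secondary Structure Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study how the accuracy of statistical (deep-learning)
    predictors of RNA secondary structure depends on the sequence similarity
    between seen (training/validation) and unseen (test) sets. Provides
    readers and writers for dot-bracket, CT, BPSEQ and FASTA records;
    similarity-stratified dataset curation (exact deduplication, greedy
    identity clustering, cross-set filtering, cross-sequence/cross-cluster/
    cross-family splits); a synthetic corpus generator with ground-truth
    structures from a deterministic Nussinov folding oracle; a compact
    sequence-to-pair neural predictor (bidirectional LSTM sequence module,
    outer-product pair transform, residual 2D convolutions, softmax pairing
    probability matrix head) trained with a two-stage cross-entropy then
    soft-F1 schedule; element-wise F1 evaluation, PGscore, and soft-F1
    variance estimates; and pairwise sequence/structure alignment analyses
    (PSI/PSSI) that quantify how generalizability decays with similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'curation.R'
    'generalizability.R'
    'metrics.R'
    'seqfold2d.R'
    'pipeline.R'
    'ppmfold-package.R'
    'rna_io.R'
    'synthgen.R'
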