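Package: rpikrls
Title: RNA-Protein Interaction Prediction with Derived String Kernels and
    Regularized Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-only prediction of RNA-protein interactions. Protein
    and RNA chains are compared with a two-layer derived string kernel
    (k-mer frequency neural responses with correlation normalization),
    pairs of chains are compared with a tensor-product pair kernel, and a
    kernel regularized least squares classifier is fitted with efficient
    leave-one-out selection of the ridge parameter. Includes stratified
    cross-validation and template-size grid search, dataset construction
    utilities (redundancy removal, length filtering, permutation-based
    negative sampling), a synthetic motif-planting data generator, and
    export of predicted interaction networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
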