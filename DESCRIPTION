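Package: eslkit
Title: Evolutionary Sparse Learning for Phylogenomic Hypotheses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic models of evolutionary hypotheses by sparse group
    LASSO logistic regression on one-hot encoded multiple sequence alignments.
    A binary hypothesis (clade membership or trait presence, coded +1/-1) is
    regressed on bit columns derived from alignment positions, with bi-level
    sparsity acting on individual positions and on whole loci (groups).
    Includes alignment encoding with monomorphic/singleton/count filters,
    hypothesis construction from class files or labeled rooted Newick trees,
    four class-balancing strategies including phylogeny-aware selection of
    negative taxa, a FISTA proximal-gradient solver with the sparse-group
    Moreau-Yosida proximal operator, k-fold cross-validation and lambda grid
    search, sparsity-score post-processing (PSS/GSS/HSS, SPS/SPP), model
    serialization, classification of new aligned sequences, and a
    deterministic synthetic-data generator with planted clade signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    ape,
    optparse,
    stats,
    utils,
    withr
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
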