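Package: mitobias
Title: Compositional-Bias Diagnostics and Bias-Aware Phylogenetics for
    Mitochondrial Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to diagnose and work around compositional bias in
    mitochondrial phylogenomics. Reads, translates and filters concatenated
    protein-coding gene alignments; computes per-taxon and per-group base and
    amino-acid composition, AT/GC skews, FYMINK/GARP ratios, the effective
    number of codons and the codon adaptation index; applies RY, six-state and
    four-state amino-acid recodings and residue masking; builds base-frequency
    and LogDet (paralinear) distance matrices and minimum-evolution trees;
    evaluates fixed topologies under GTR- and JTT-family models with discrete
    gamma rates via a pruning likelihood engine; performs RELL-based
    Kishino-Hasegawa and Shimodaira-Hasegawa topology tests and the Goldman
    (Cox) parametric-bootstrap goodness-of-fit test; estimates posterior site
    rates and excludes fast-evolving sites; and simulates protein-coding
    alignments on a known tree under a non-stationary model in which one clade
    shifts toward a T-rich, C-poor composition, so that the whole analysis
    chain can be exercised on data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
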