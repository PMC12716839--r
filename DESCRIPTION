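Package: GPCRome
Title: Profile-HMM Discovery and Evolutionary Classification of GPCR Repertoires
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing G-protein-coupled receptor (GPCR)
    repertoires in predicted proteomes. Implements a two-track screen
    (family-specific profile HMMs plus a seven-transmembrane topology-grammar
    HMM), multi-criterion candidate validation (reference-homology check,
    six-to-eight transmembrane-helix retention, isoform and fragment
    removal), iterative refinement with lineage-specific cluster HMMs,
    all-vs-all similarity-graph clustering with force-directed layout and
    convex-cluster family calls, domain-architecture and micro-motif
    analysis of the HRM/GAIN/7TM module, and Dollo parsimony mapping of
    family gains and losses on a species tree. A synthetic-proteome
    generator with full ground truth makes the whole pipeline testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    ape,
    igraph,
    mclust
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'pairwise.R'
    'clans.R'
    'topology.R'
    'hmm.R'
    'domains.R'
    'evolution.R'
    'msa.R'
    'seqio.R'
    'screen.R'
    'synthetic.R'
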