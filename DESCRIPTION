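Package: ftszprov
Title: Tracing the Origin of FtsZ/Tubulin Family Paralogs with Profile
    HMMs, Curated Alignments and Desk-Scale Phylogenetics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A comparative-genomics toolkit for tracing the provenance of
    protein-family paralogs such as the FtsZ/tubulin family. Implements
    profile hidden Markov model construction, Gumbel-calibrated search and
    domain-envelope detection; taxonomically balanced dataset curation
    (coverage filtering, CD-HIT-style redundancy clustering, gap-threshold
    and entropy-based alignment trimming); a built-in progressive aligner;
    neighbor-joining phylogenies with bootstrap supports, midpoint rooting
    and low-support collapse; gene-neighborhood domain-abundance analysis;
    and the domain-anchored C-terminus cross-search that tests where a
    paralog's diagnostic tail came from. A bundled simulator of
    modular-domain family evolution over a species tree (duplication, loss,
    lateral transfer, C-terminus replacement, clade-specific gene
    neighborhoods) provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'msa.R'
    'curate.R'
    'align.R'
    'phmm.R'
    'context.R'
    'phylo.R'
    'cterm.R'
    'proteinset.R'
    'simulate.R'
    'emit.R'
    'ftszprov-package.R'
    'pipeline.R'
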