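Package: hybridbin
Title: Subgenome Binning and Allele-Aware Analysis for Hybrid Polyploid
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving hybrid aneuploid polyploid genome
    assemblies such as modern sugarcane cultivars: contig quality control
    (Hi-C misjoin detection, artifactual k-mer and contamination filters,
    gene-model retention rules), six-group origin binning of contigs by
    parent (read depth and parental-specific 21-mers) and ancestry
    (depth t-tests, reference similarity, Hi-C based recombinant
    detection), allele-table construction by best-hit anchoring, synteny
    and coordinate overlap, homoeolog expression-dominance analysis, and
    Nei-Gojobori synonymous substitution rates. A synthetic
    hybrid-aneuploid genome simulator with full ground truth drives every
    stage, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
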