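Package: smoltmir
Title: Small RNA-Seq miRNA Discovery, Annotation, Quantification and Target
    Prediction for Salmonid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing pipeline for building a miRNA
    repertoire from paired-end reads: paired-read reconciliation, quality and
    adapter filtering, collapsing to unique sequences with per-sample counts,
    exact genome mapping and locus building, minimum-free-energy hairpin
    folding with a brute-force oracle, annotation of pri/pre/mature/star
    records under the standard deep-sequencing miRNA criteria (Dicer 2-nt
    3' overhang, 5'-processing consistency, 65-nt precursor minimum,
    expression gate, repeat and annotation masking), homology classification
    against reference mature miRNA sets by ungapped local alignment with
    Karlin-Altschul E-values, family clustering with copy-number and
    abundance statistics, and seed plus duplex-hybridisation-energy target
    prediction on 3' UTRs with Gumbel-calibrated p-values. A synthetic-data
    generator provides ground truth (planted hairpins, duplicate gene copies,
    decoy loci, planted target sites) for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
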