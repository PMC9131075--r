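Package: tandemscan
Title: Detection and Divergence Analysis of Tandemly Duplicated Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies tandemly duplicated gene (TDG) clusters in annotated
    genomes from pairwise coding-sequence homology with e-value, bit-score-ratio
    and coverage thresholds and an intervening-gene rule; quantifies divergence
    between duplicate copies at the coding level (Nei-Gojobori Ka/Ks with
    Jukes-Cantor correction), the expression level (Pearson correlation of TPM
    profiles, tau specificity, breadth and level against a random-pair null) and
    the regulatory level (local-alignment promoter similarity against a
    random-pair null); classifies clusters as core, shared or private across
    genotypes via orthogroups; tests Pfam-domain and GO-term over-representation
    with Fisher exact tests and FDR control; and calls duplicate-retention fates
    (sub-functionalization, genetic redundancy, neo-functionalization). Includes
    a multi-genotype synthetic-data generator with planted ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
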