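Package: kinsig
Title: Population-Genetic Signatures of Kin Selection in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for the population-genetic footprint of kin selection in
    natural bacterial populations. Relaxed purifying selection on cooperative
    (public-good) genes, relative to private genes expressed at the same rate,
    elevates both polymorphism and divergence; this package computes the
    per-gene statistic battery (nucleotide diversity at all, synonymous and
    nonsynonymous sites, Tajima's D, Fu and Li's D*/F*, McDonald-Kreitman
    tables with neutrality index and direction of selection, NG86 Ka/Ks
    against an outgroup pseudogenome), compares cooperative, private and
    background gene classes with Welch ANOVA/Games-Howell and
    Kruskal-Wallis/Dunn batteries, controls for conditional expression with a
    bootstrap null for gene-set co-expression, tests enrichment of deleterious
    (stop-gain and frameshift) mutations, and back-calculates average
    relatedness r from the ratio of class median polymorphism. A built-in
    Wright-Fisher forward simulator under a relaxed-selection model generates
    complete synthetic inputs (VCF, GFF3, FASTA, expression matrix, truth
    table) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
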