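Package: mitocomp
Title: Comparative Analysis of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated insect mitochondrial
    genomes: nucleotide composition and strand-skew statistics, codon usage
    and relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial code, gene-order rearrangement detection by signed
    breakpoint analysis against the ancestral insect arrangement, gene
    overlap and intergenic-spacer accounting, control-region localization and
    tandem-repeat detection, pairwise p- and closed-form GTR distances with
    substitution-saturation regression, Nei-Gojobori nonsynonymous divergence
    (Ka), and construction of concatenated phylogenetic datasets with codon
    position partitions. Includes a seeded simulator of annotated mitogenomes
    and GTR-diverged sequence pairs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
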