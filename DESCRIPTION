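Package: botryphylo
Title: Phylogeographic Inference for mtCOI Haplotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for mitochondrial phylogeography of
    colonial ascidians and similar haploid uniparental markers. Reads
    aligned mtCOI haplotype data with a hierarchical population/region
    map and provides per-population polymorphism and neutrality
    statistics (haplotype and nucleotide diversity, Watterson's theta,
    Tajima's D, Fu's Fs, Ramos-Onsins and Rozas' R2), hierarchical
    AMOVA with permutation-tested fixation indices and pairwise F_ST
    matrices, median-joining haplotype networks, fixed-tree discrete
    ancestral location reconstruction, coalescent simulation of
    demographic scenarios with ghost lineages and admixture under
    HKY+I, and approximate Bayesian computation model choice with a
    two-round confidence-interval scenario tournament. Includes a
    synthetic-study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    MASS,
    nnet,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
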