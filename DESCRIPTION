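Package: tephrimark
Title: Phylogenomic Marker Capture, Concordance and Diagnostic Primer
    Screening for Fruit-Fly Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, simulation-driven implementation of a genome-scale
    marker workflow for tephritid (true fruit fly) phylogenomics: probe-based
    harvesting of conserved single-copy loci (BUSCO/UCE/AHE-style) from genome
    assemblies with duplicate removal and 400-bp flank retention;
    taxon-occupancy supermatrix construction with alignment summary statistics
    (parsimony-informative sites, missing data); distance-based gene-tree
    estimation with column bootstrap, Robinson-Foulds concordance and
    classical multidimensional scaling of tree space; phylogenetic
    informativeness profiling over time; and a species-specific diagnostic
    marker screen (sliding-window CDS fragmentation, cross-genome exclusion,
    primer design, in-silico PCR with specificity verdicts). A synthetic
    genome generator with full truth tables makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
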