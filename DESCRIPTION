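Package: tagpower
Title: Linkage Disequilibrium Profiling, Tag SNP Selection, Array Coverage
    and Case-Control Power for Sequencing-Era Association Study Design
Version: 0.1.0
Authors@R:
    person("Maren", "Winters", email = "mwinters@example.org",
           role = c("aut", "cre"))
Description: Evaluates next-generation association-study designs on phased
    haplotype panels: pairwise r-squared profiles within inter-marker
    windows stratified by minor-allele-frequency class, greedy pairwise
    tag-SNP selection with bins and untaggable-SNP detection, coverage of a
    cohort by a fixed genotyping-array manifest, and Monte-Carlo power of
    the two-degree-of-freedom genotypic chi-square test under dominant,
    additive, multiplicative and recessive disease models, with a
    noncentral chi-square analytic oracle.  Includes a synthetic-panel
    generator (neutral folded site-frequency spectrum imposed on a
    founder-copying mosaic with block-structured, distance-decaying LD) and
    discovery-subsample array ascertainment, so the whole pipeline runs
    without external data; real phased VCF, hap/legend, BED and manifest
    files are supported throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
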