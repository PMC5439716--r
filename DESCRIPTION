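Package: ssrmine
Title: Mining and Characterization of Polymorphic Microsatellite Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico discovery of polymorphic simple sequence repeat (SSR)
    markers from a reference genome assembly plus low-coverage resequencing
    reads of other accessions, and the downstream marker-characterization
    statistics used to validate them. Detects maximal perfect tandem repeats
    (1-8 bp motifs) with MISA-style minimum-unit criteria, trims
    repeat-containing fragments to fixed flanks, genotypes repeat-unit counts
    from spanning reads in SAM/BAM alignments and classifies loci as not,
    slightly or clearly polymorphic, screens flanks for primer feasibility,
    computes allele number, expected and observed heterozygosity, polymorphism
    information content and null-allele frequency, builds neighbor-joining and
    UPGMA dendrograms from binary-encoded genotypes, and tests Mendelian
    segregation ratios in mapping populations. A deterministic simulator
    generates genomes with planted repeats, cultivar read sets and genotype
    tables with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    ape,
    phangorn,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
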