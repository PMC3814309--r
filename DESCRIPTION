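Package: uvloh
Title: Simulation and Analysis of UV-Induced Mitotic Recombination and
    Loss of Heterozygosity in Diploid Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide analysis of mitotic recombination induced
    by UV in a SNP-heterozygous diploid. Provides a forward simulator of
    pyrimidine-dimer formation, conversion of lesions to single- or
    double-sister-chromatid breaks, and repair by synthesis-dependent strand
    annealing, double-Holliday-junction resolution, or break-induced
    replication; an allele-specific hybridization-ratio caller that segments
    per-SNP zygosity into loss-of-heterozygosity blocks with minimal and
    maximal transition bounds; a dual-sector event classifier (crossover,
    break-induced replication, gene conversion; 3:1, 4:0 and hybrid tracts;
    single- versus double-sister-chromatid breaks); a statistics layer for
    conversion-tract lengths, detection-corrected and control-normalized event
    rates, regional expectation tests and permutation-based element
    enrichment; and the three-marker chromosome XII assay for crossovers,
    break-induced replication and intrachromosomal events in the ribosomal DNA
    cluster.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
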