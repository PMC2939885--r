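Package: plastidkit
Title: Chloroplast Genome Assembly, Structure, Codon Usage, Heteroplasmy
    and Transcription-Unit Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for plastid (chloroplast) genome analysis built
    around pyrosequencing-era data: simulation of circular quadripartite
    genomes and error-prone long reads, screening of chloroplast-derived
    reads from mixed pools, iterative contig elongation, homopolymer-run
    inventories, detection of the quadripartite architecture and
    IR-junction gene context, dispersed-repeat and small-inversion
    (stem-loop) discovery, codon-usage statistics (RSCU, amino-acid and
    positional base composition, start-codon audit), intravarietal
    (heteroplasmic) SNP and indel calling from read pileups, and
    assignment of poly- and monocistronic transcription units from
    polyT-primed cDNA reads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
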