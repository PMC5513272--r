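Package: poolMHC
Title: Pooled-Amplicon MHC Genotyping and Population Genetics for Seabird Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for major histocompatibility complex (MHC)
    amplicon genotyping from pooled, barcoded 454-style pyrosequencing reads,
    with downstream population genetics. Implements a six-rule read-cleaning
    cascade (length, reference alignment, dereplication, per-barcode singleton
    removal, Phred quality, frameshift filtering), per-barcode diversity and
    neutrality statistics (segregating sites, haplotype and nucleotide
    diversity, Tajima's D, Fu's Fs, Nei-Gojobori Ka/Ks), pairwise Phi-ST
    differentiation with permutation significance, Mantel tests of isolation
    by distance against great-circle distances, and a cross-barcode allele
    catalog (shared, private and trans-species alleles). A synthetic-data
    generator emulates pooled-colony study designs (coalescent allele pools
    with a tunable dN/dS bias, stepping-stone population structure along a
    coastline, and 454-style substitution, homopolymer-indel and chimera
    errors) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
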