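Package: mitodiv
Title: Mitochondrial Genome Diversity: Segments, Polymorphism and Heteroplasmy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing the genetic diversity of small circular
    genomes, built around the mitochondrial genome and its control region.
    Detects polymorphic sites in multiple sequence alignments and classifies
    them as transition-, transversion- or indel-containing; delimits conserved
    and variable segments of the control region with an exact window p-value;
    computes per-gene variability indices and weighted allele-frequency bin
    tables; calls heteroplasmic (intra-individual) variants from read pileups
    with coverage- and frequency-based thresholds; builds UPGMA phylogenies
    from p-distance, Tamura-Nei or Tamura 3-parameter distances with bootstrap
    support; and joins inter- and intra-individual variability into a single
    comparative report. A synthetic-data generator produces haplotype panels,
    genome quartets and pileups with serialized ground truth so every stage
    can be tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    S4Vectors,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
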