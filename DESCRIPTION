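Package: startloss
Title: Isoform-Specific Start-Loss Candidate Genes, Isoform Usage, and
    Founder-Haplotype Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects genes whose shorter protein isoform is an exact in-frame
    N-terminal truncation of the longer isoform, so that a single start-codon
    mutation can ablate one isoform while sparing the other. Provides the
    candidate filter cascade (containment, essentiality, disease annotation,
    truncation length), a unique-exon isoform-usage ratio statistic with a
    cross-tissue variability filter, dual-isoform variant-consequence
    annotation in HGVS-like notation (missense, start-loss, stop-gain and
    frameshift termination scanning), runs-of-homozygosity calling with
    PLINK-style parameters, shared founder-haplotype intersection, genetic-map
    interpolation and mutation-age estimation in generations, together with
    seeded synthetic-data generators (genome/annotation, expression counts,
    founder probands) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
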