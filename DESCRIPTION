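Package: tandem5ss
Title: Analysis of Competing Tandem 5' Splice Sites from RNA-seq and CLIP-seq Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrated analysis of alternative 5' splice site
    (A5SS) events with two competing tandem donors sharing one acceptor.
    Provides grid-based Bayesian estimation of the inclusion fraction (PSI)
    from isoform-diagnostic junction counts, Bayes-factor comparison of two
    conditions with the standard num_inc/num_exc/delta-psi/bayes-factor
    filters, classification of events by perturbation response, strand-aware
    normalized CLIP-tag density metaprofiles in a 400-nt window around each
    donor with an eight-section argmax report, splice-donor strength and
    exonic splicing enhancer (ESE) motif scoring, block-scanning mutant
    design, and a synthetic-data generator that emulates the downstream
    products of a knockdown RNA-seq / CLIP-seq experiment so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
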