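Package: proxireg
Title: Proximity-Labelling Partner Selection and Chromatin Pile-Up Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying molecular partners of chromatin-bound
    baits from proximity-dependent biotin-labelling proteomics, and for
    characterising their spatial relationship to regulatory loci.
    Implements spectral-count candidate filtering with negative-control
    enrichment ratios and top-3 peptide-area quantification, RPGC
    normalisation and ChIP/input enrichment tracks with site-centred and
    metagene pile-up profiles, and Hi-C aggregate analyses (average-loop
    pile-ups with shifted-control background normalisation and rescaled
    local contact-domain pile-ups) with the central-block loop-strength
    statistic. A synthetic-data generator reproduces the statistical
    structure each analysis assumes, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
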