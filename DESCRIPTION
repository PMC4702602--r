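Package: exoorg
Title: Positional Organization of Transcription Factor Complexes from ChIP-exo
    Peak Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining transcription-factor binding locations from
    ChIP-exo tag 5'-end data at near-base-pair resolution and for analysing the
    positional organization of factors around their DNA motifs. Implements
    strand-separated Gaussian-smoothed peak calling with an exclusion zone,
    plus/minus peak pairing, binomial enrichment testing against an input
    control with Benjamini-Hochberg correction, cross-condition consolidation
    of binding locations and intersection with external event lists, IUPAC and
    position-weight-matrix scanning with exact p-values, motif-anchored
    composite cross-link profiling and cross-link point estimation, composite
    motif (TG[N7-8]WGATAA) spacing analysis, E-box composition classification,
    homotypic binding-site clustering, ChIP-exo/ChIP-seq concordance measures,
    and differential-occupancy kinetic classification. Includes a synthetic
    ChIP-exo/ChIP-seq data generator built on an explicit cross-link geometry
    model, with ground-truth tables for benchmarking the full calling chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
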