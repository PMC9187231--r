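Package: loopex
Title: Simulation and Contact-Map Analysis of Cohesin Loop-Extrusion Barriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how transcription, centromeres and stalled
    replication forks act as barriers to cohesin-mediated loop extrusion in a
    small (yeast-like) genome. Provides a one-dimensional stochastic
    loop-extrusion simulator with directional barriers and condition presets
    (G2/M wild type, transcription inhibition, loader/unloader depletion,
    hydroxyurea arrest), renderers for binned Hi-C-like contact maps and
    ChIP-like occupancy tracks with known ground truth, and the matching
    analysis stack: pairs binning, coverage-sqrt normalization, contact
    probability curves, insulation scores, aggregate peak analysis, local
    background loop calling, corner-score domain calling, anchored
    cis-interaction quantification, and rule-based feature classification
    from fold-enrichment tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
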