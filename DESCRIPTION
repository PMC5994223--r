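Package: ishquant
Title: Quantification of Single-Pair Probe In Situ Hybridization Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-quantitative analysis of single-pair probe in situ
    hybridization (BaseScope-style) experiments. Provides a designer for
    exon-junction-specific probe pairs (one 18-25 nt oligo spanning the
    splice junction, one immediately adjacent) with isoform-specificity
    screening; a synthetic two-channel fluorescence field simulator with
    full ground truth (DAPI-like nuclei, diffraction-limited FastRED-like
    puncta, knockout-like background, clump artifacts); a quantification
    pipeline that segments nuclei, calibrates intensity and diameter
    thresholds from negative-control sections, detects dots, assigns each
    dot to the closest nucleus and computes dots per area, percent positive
    cells and dots per positive cell; and the matching statistical layer:
    one- and two-way ANOVA with Tukey multiple comparisons, computable from
    raw replicates or from printed mean/SEM/n summaries, plus relative
    isoform abundance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
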