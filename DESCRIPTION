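Package: mesoframe
Title: Y-Maze Behavior, Miniscope Calcium Trace, and Mesofrontal Morphology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying memory-guided navigation and its
    neural correlates: spontaneous-alternation scoring of Y-maze sessions,
    event detection and position-binned ensemble analysis of 30 Hz dF/F
    calcium traces recorded with head-mounted miniature microscopes,
    stimulation-response imaging summaries, and confocal quantification of
    dopaminergic axons, synaptic boutons and labeled somata with per-animal
    normalization. Ships seeded synthetic-data generators with exhaustive
    ground truth so every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071,
    car,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
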