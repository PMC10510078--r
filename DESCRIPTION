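Package: enrichlib
Title: Design of Information-Enriched Enzyme Variant Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing focused ("information-enriched") enzyme
    variant libraries. Ingests per-mutation stability predictions (delta-delta-G
    matrices), multiple-sequence-alignment conservation profiles and predicted
    flexibility profiles; excludes predicted-deleterious substitutions to build
    an allowed mutation set; quantifies how graded sequence-space cuts retain
    known beneficial mutations (retention curves and grids with random
    baselines); translates surviving mutations into a synthesizable oligo pool
    with gene fragmentation, one-mutation-per-oligo encoding and amplification
    primer design; and classifies sequenced pool members against the design as
    wild-type, single designed mutation or multiple mutations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
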