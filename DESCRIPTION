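Package: schemaRSA
Title: Split-Half Representational Similarity Analysis of Schema-Based
    Motor Sequence Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the compatibility of a new motor
    sequence with a previously acquired cognitive-motor schema shapes
    multivoxel activation patterns. Implements serial reaction time task
    (SRTT) sequence and schema-compatibility construction, event timeline
    generation, a synthetic BOLD and behavioural data generator with
    controllable pattern-reliability structure, per-run ROI general linear
    models with a canonical double-gamma haemodynamic response, exhaustive
    split-half cross-validated pattern similarity per key/ordinal-position
    pairing, and the group-level statistical battery (mixed group-by-position
    ANOVA with Greenhouse-Geisser/Huynh-Feldt sphericity correction,
    Levene-gated independent t-tests, paired edge-effect contrasts, and
    Benjamini-Hochberg false discovery rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
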