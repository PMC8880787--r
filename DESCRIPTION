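Package: pragmap
Title: Corpus Annotation and Group Statistics for Mapping Pragmatic Language Impairment
Version: 0.1.0
Authors@R:
    person("pragmap", "developers", role = c("aut", "cre"),
           email = "pragmap@example.org")
Description: Tools for span-based lexicogrammatical annotation of
    morphologically analyzed spoken-language transcripts, built around a
    systemic-functional 159-tag annotation scheme. Provides dictionary-based
    leftmost-longest span tagging, multi-channel IOB2 encoding and decoding, a
    trainable sequence labeler with span-level precision/recall/F1 evaluation,
    KWIC concordancing, per-subject occurrence rates with Welch two-sample
    group comparison, and a seeded synthetic-corpus generator with planted
    group-specific tag rates for power and calibration studies. A command-line
    interface ties the stages into an annotate-train-evaluate-compare
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
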