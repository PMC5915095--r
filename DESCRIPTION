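Package: massderep
Title: Dereplication of Complex Polyphenolic Mixtures by Exact-Mass Formula
    Assignment and Bioactivity Profile Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dereplicating complex natural-product mixtures such as
    water-soluble lignin derivatives. Reconstructs neutral masses from
    negative-mode high-resolution mass-spectrometry peak lists, assigns CHO
    molecular formulas by exhaustive enumeration under elemental-ratio
    constraints, classifies formulas on the Van Krevelen plane, converts
    radioligand binding panel results into a boolean target profile, mines a
    ChEMBL-like compound/assay store for formula matches, hashes activity
    values into boolean bioactivity fingerprints, scores each candidate
    compound against the experimental profile with an additive fit score, and
    summarises Bemis-Murcko scaffold distributions. A seeded synthetic-data
    generator provides ground-truth inputs for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
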