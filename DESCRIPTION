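Package: markermine
Title: Self-Organized Semantic Text Mining for Biomarker and Phenotype Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A literature-based discovery pipeline that mines a document
    collection for candidate disease biomarkers and phenotypes. Documents are
    recognized against a lexicon of synonym groups linked into a seven-level
    hypernym taxonomy, projected into an entropy-weighted content space, and
    categorized on a Kohonen self-organizing map whose labeled regions act as
    semantic main topics. Out-of-vocabulary terms receive constructed hypernyms
    by weighted cross-tabulation against known terms; candidate terms are
    screened by comparing their evidence-document subsets against clustered
    reference models and scored with an empirical confidence level. Includes
    benchmark evaluation (exact/partial matching, precision/recall/novelty,
    match-type triage) and a seeded synthetic-corpus generator with ground-truth
    manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
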