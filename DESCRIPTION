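Package: enzchemkit
Title: Corpus Tools, Sieve Normalization and Reaction-Pair Chemistry for
    Enzyme Function Text Mining
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for text-mined enzyme chemistry: reading, writing,
    validating and summarising BioC XML corpora annotated with chemical and
    protein mentions and chemical-conversion relations; conversion between
    mention annotations and IOB2 sequence-labelling formats; a sieve-based
    chemical normalization pipeline over TSV lexicons with abbreviation
    resolution, cross-lexicon pivot mapping and pH 7.3 ChEBI remapping;
    enumeration and rendering of binary chemical-pair and ternary
    enzyme-tuple relation instances; span-level precision/recall/F1
    evaluation for named entity recognition, normalization, relation
    extraction and end-to-end output (with ontology-relaxed ChEBI matching);
    and downstream comparison of predicted chemical pairs against
    reaction-database reference pairs, including a
    maximum-common-substructure atom-conservation metric. Deterministic
    synthetic-fixture generators make every component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    xml2,
    igraph,
    ggplot2,
    generics,
    jsonlite
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
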