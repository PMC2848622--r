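Package: chemlex
Title: Dictionary-Based Chemical Named-Entity Recognition and Lexicon Curation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for identifying small molecules and drugs in free text
    with a curated chemical dictionary. Covers dictionary ingestion (TSV and a
    minimal SKOS RDF/XML reader), rule-based term filtering and rewriting
    (syntactic inversion, possessive stripping, long/short-form splitting),
    concept merging on shared CAS/InChI/cross-reference identifiers,
    name-to-formula consistency checks, a chemical-aware tokenizer with
    bracket and punctuation stripping, leftmost-longest token-sequence concept
    matching, rule-based homonym disambiguation using synonym and keyword
    context, exact-boundary evaluation against brat-style gold annotations
    with per-class recall and automated error categorisation, and seeded
    synthetic dictionary/corpus generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
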