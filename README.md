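# chemlex

Dictionary-based identification of small molecules and drugs in free text,
plus the lexicon curation that makes it work.

Chemical named-entity recognition differs from most biomedical NER in that
punctuation carries meaning: commas, hyphens, plus signs and brackets are
part of systematic names ("2,4-dinitrophenol", "[Ca(2+)]i"). chemlex is for
text-mining practitioners who have a multi-source chemical dictionary
(concepts with a preferred term, synonyms, and CAS / InChI / cross-reference
identifiers) and need to (a) curate it for text mining and (b) tag and
ground mentions in documents, with honest exact-boundary evaluation.

The package covers, end to end:

* **Dictionary ingestion** — TSV and a minimal SKOS RDF/XML reader
  (`read_dictionary()`), canonical writing, validation of identifier
  formats (CAS `dd..d-dd-d`, `InChI=` prefixes, prefixed cross-references).
* **Curation** — removal rules (single trivial tokens such as "T" or roman
  numerals; suppression features such as dosages, "unspecified", terminal
  "NOS"; a reviewed frequent-term stoplist), rewrite rules (syntactic
  inversion "acid, X" → "X acid", possessive stripping "Ringer's" →
  "Ringer", long/short-form splitting "Hydrogen chloride (HCL)"),
  transitive concept merging on shared identifiers, cross-dictionary
  overlap, and name-to-formula consistency checks (chloride ⇒ Cl in the
  formula, hydrate ⇒ waters of hydration, ...).
* **Matching** — a chemical-aware tokenizer (punctuation kept inside
  tokens, then stripped where it is clearly punctuation) feeding a
  token-sequence index scanned case-insensitively, word-order sensitively,
  leftmost-longest, with non-informative tokens ("of", "the", "and", "in")
  skipped in keys but covered by spans.
* **Disambiguation** — dictionary homonyms and "potential homonyms"
  (shorter than 5 characters or digit-free, like "As" for arsenic) are
  kept only with a co-mentioned synonym of the same concept or a rare
  "keyword" token from the concept's long-form names in the same text.
* **Evaluation** — exact-boundary precision / recall / F
  (P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R)) against brat-style gold
  standoff with entity classes IUPAC / PART / SUM / TRIV / ABB / FAM,
  per-class recall, and automated error categorization (partial match,
  removed by disambiguation/stoplist, tokenization error, not in
  dictionary).
* **Synthetic fixtures** — seeded generators for dictionaries and
  annotated corpora with manifest-backed planted structure (homonym traps,
  partial-name traps, feature terms, common-word synonyms), so the whole
  pipeline is testable without licensed dictionary data.

See `vignettes/chemical-term-identification.Rmd` for the methods account.

## Worked example

```r
library(chemlex)

d <- read_dictionary(system.file("extdata", "example_dictionary.tsv",
                                 package = "chemlex"), "tsv")
d
#> <chem_dictionary> 5 concepts, 8 terms (8 active), 10 identifiers

rw <- apply_rewrite_rules(apply_removal_rules(d)$dictionary)
rw$n_added       # "acid, acetylsalicylic" inverted; "(GABA)" split; "Ringer's" stripped
#> [1] 3

docs <- c(abs1 = paste("Patients received acetylsalicylic acid (aspirin)",
                       "dissolved in Ringer lactate. GABA levels fell."))
ann <- disambiguate(tag_corpus(docs, build_index(rw$dictionary)),
                    docs, rw$dictionary)
ann[, c("start", "end", "surface", "concept_ids", "status", "evidence")]
#>   start end              surface concept_ids status evidence
#> 1    18  38 acetylsalicylic acid       EX001   kept  synonym
#> 2    40  47              aspirin       EX001   kept  synonym
#> 3    62  76       Ringer lactate       EX005   kept  keyword
#> 4    78  82                 GABA       EX004   kept  keyword
```

"aspirin" and "acetylsalicylic acid" license each other as co-mentioned
synonyms of EX001; "GABA" (short, digit-free — a potential homonym) is kept
because it was indexed from the split of "gamma-aminobutyric acid (GABA)"
and a rare keyword of that concept occurs in the text. Note the span of
"aspirin" excludes the parentheses: spans cover the token core left after
punctuation stripping.

The four-stage pipeline on a seeded synthetic corpus with planted traps:

```r
fx <- generate_dictionary(fixture_spec(seed = 7))
co <- generate_corpus(fx)
run_pipeline(fx$dictionary, co$docs, co$gold, stoplist = co$manifest$stoplist)
#>           stage tp fp fn precision recall f_score
#>     unprocessed 61 22  4      0.73   0.94    0.82
#>        filtered 61 18  4      0.77   0.94    0.85
#>  frequent_terms 61 10  4      0.86   0.94    0.90
#>  disambiguation 61  4  4      0.94   0.94    0.94
```

Each curation stage removes its planted false positives — feature terms at
`filtered`, common-word synonyms at `frequent_terms`, evidence-free homonym
traps at `disambiguation` — while the four remaining errors on each side
are the planted partial-name traps, which exact-boundary matching cannot
resolve by construction.

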