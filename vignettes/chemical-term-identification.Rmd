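---
title: "Dictionary-based chemical term identification with chemlex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-based chemical term identification with chemlex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemlex)
```

## The problem

Finding chemical names in free text is harder than most named-entity tasks
because punctuation is load-bearing: commas, hyphens, plus signs and
parentheses are part of systematic names ("2,4-dinitrophenol", "[Ca(2+)]i"),
so a tokenizer that treats them as delimiters destroys the very strings a
dictionary could match. chemlex implements the dictionary-based approach to
chemical *term identification* — recognition plus grounding of each mention
to a dictionary concept — together with the lexicon curation steps that make
a raw multi-source dictionary usable for text mining: rule-based term
removal and rewriting, concept merging on shared identifiers, frequent-term
stoplisting, and rule-based homonym disambiguation. Performance is measured
with exact-boundary precision/recall/F against brat-style gold annotations
over six entity classes (IUPAC, PART, SUM, TRIV, ABB, FAM).

## The matching model

A dictionary maps concepts (one preferred term, synonyms, CAS/InChI/
cross-reference identifiers) to token sequences. Matching is
**case-insensitive, word-order sensitive and largest match**: scanning left
to right, the longest indexed token sequence starting at the current token
is emitted and scanning resumes after it, so mentions never overlap. Four
non-informative tokens ("of", "the", "and", "in") are deleted from index
keys and skipped during comparison, but a mention's span still covers them
in the text. We read "largest match" as greedy leftmost-longest rather than
a globally optimal tiling; that is the standard behaviour of
concept-recognition indexers, and the brute-force oracle used in the test
suite implements the same policy by exhaustive window enumeration.

### Tokenization and normalization

Everything that is not a letter or a digit delimits tokens, *except* full
stops, commas, plus signs, hyphens, single quotation marks and all brackets,
which stay inside tokens. Each token is then normalized: trailing full stops
and commas are stripped; brackets with no partner inside the token are
removed; brackets surrounding the whole token are removed; these three steps
repeat to a fixpoint, after which one suffix from a configurable list may be
removed and the token is lower-cased. Bracket matching is local to the token
(a simple stack over `()[]{}`), which reproduces the known failure mode
where "[Ca(2+)]i" keeps its brackets — the trailing "i" prevents
surround-stripping — so a dictionary entry "Ca(2+)" cannot match inside it.

One design point deserves emphasis. Offsets are 0-based half-open and always
refer to the raw document, but a mention's reported span covers the matched
tokens' **cores**: the part of each surface that survives the punctuation
and bracket stripping. Without this, every sentence-final mention would
carry its full stop ("aspirin." instead of "aspirin") and exact-boundary
evaluation would fail systematically, which is plainly not how such systems
behave in practice. Suffix removal and lower-casing are purely key-side and
never move spans. When stripping removes interior characters (so the core is
no longer one contiguous substring), the span falls back to the full token.

### Term filtering and rewriting

Three removal rules mark terms as `removed` (never deleted, so every
decision is auditable and the filtered dictionary round-trips through TSV):

1. **single trivial token** — after tokenization and stop-word removal a
   single token remains that is one character, an arabic integer, or a
   roman numeral ("T" as a tritium abbreviation). Roman numerals are
   recognized in strict subtractive notation, case-insensitively, up to a
   configurable maximum (default 3999) with an allowlist escape hatch,
   because the rule would otherwise also remove letter codes such as "CL"
   that happen to be valid numerals — a known, deliberate trade-off.
2. **suppression features** — dosages (a number followed by %, percent,
   g/gram(s), microgram(s)/mcg/µg/ug, ml/milliliter(s); ranges count if
   either endpoint matches), "not otherwise specified"/"not
   specified"/"unspecified", terminal "NOS" after a comma or bracketed
   after a space, "other" at a term boundary, "deprecated", "unknown",
   "obsolete", "miscellaneous", and a leading "no ". Patterns are applied
   in that order and the first match is logged; order only affects the
   logged label, never the removal decision.
3. **stoplist** — surfaces judged to be general English during review of
   the most frequent matched terms in a reference corpus.
   `frequent_term_candidates()` produces the ranked candidates (raw
   occurrence counts, ties broken lexicographically, top 500 by default);
   the human judgment itself is out of scope, the package only consumes the
   reviewed list.

Three rewrite rules add synonyms without touching originals: syntactic
inversion of comma-inverted forms ("acid, gamma-vinyl-gamma-aminobutyric" to
"gamma-vinyl-gamma-aminobutyric acid"; segments reverse last-to-first, and
commas inside brackets never split), possessive stripping ("Ringer's
lactate" to "Ringer lactate"), and long/short-form splitting ("Hydrogen
chloride (HCL)" to "Hydrogen chloride" plus "HCL"). Rewrites apply to
source terms only — no chaining — since chaining would invent forms the
curation procedure never produced; case-insensitive duplicates within a
concept are skipped, which makes the operation idempotent.

### Concept merging and identifier checks

Concepts merge when they share a CAS number, an identical prefixed
cross-reference (same source database), or an InChI string; merging is the
transitive closure of that relation, implemented with union-find and tested
against a brute-force closure oracle. Because merged entities were not
manually re-curated in the workflow this package models, the choice of
preferred term after a merge is deliberately a deterministic arbitrary rule:
the preferred term of the lexicographically smallest member concept id.
Cross-dictionary overlap deliberately uses only CAS and InChI (not
cross-references), mirroring how the dictionaries' overlap figure is
defined. CAS numbers are validated by format only (`2-7 digits - 2 digits -
1 digit`); checksum validation is out of scope because CAS values function
as join keys here, not as curated fields.

The name-to-formula consistency check reproduces the automatable part of
structure-aware curation: for names containing chloride/bromide/iodide/
fluoride the formula must contain the halogen; nitrite/nitrate require N;
sulfate/sulphate/sulfite/sulphite require S; hydrate/dihydrate require at
least one/two waters of hydration (parsed from a `·nH2O` or `.nH2O`
suffix). Concepts without a formula are skipped with a marker rather than
flagged — in multi-source chemical lexicons only a small minority of
entries carry structure information, and absence of a formula is not
evidence of an error. Formula parsing accepts plain Hill notation plus the
hydrate suffix and rejects anything else loudly; element presence is all
the checks need, so parenthesised groups and charges are out of scope. The
conversion of names to structures with commercial software — the final
robot step in the modelled workflow — is explicitly not reproduced.

## Homonym disambiguation

A term is a *dictionary homonym* if it maps to more than one concept; if it
is the preferred term of a concept it is treated as unambiguous for that
concept. Dictionary-unique terms are still *potential homonyms* when they
are shorter than 5 characters or contain no digit — the "As"-for-arsenic
situation. A (potential) homonym mention survives only with contextual
evidence: (1) a different term of the same concept annotated in the same
piece of text, or (2) a concept keyword — a token from the concept's
long-form names occurring fewer than 1000 times in the whole dictionary —
present among the text's tokens. Removed mentions are flagged, never
deleted, and kept dictionary homonyms narrow their concept ids to the
evidenced concepts (no tiebreak is imposed when several concepts are
evidenced).

Three semantics were genuinely open and are exposed as configuration:

* **"shorter than five characters or no digit"** is implemented literally
  (`digit_rule = "or"`, the default) with an `"and"` variant available. The
  literal reading makes almost every trivial name a potential homonym; it
  is reconciled with the high recall such systems achieve on trivial names
  by the next switch.
* **self-evidence** (`self_evidence = TRUE`, default): a mention's own
  tokens may satisfy the keyword condition. A long trivial name like
  "chloroquine" is its own long-form name, its token is rare
  dictionary-wide, and the mention therefore licenses itself; without
  self-evidence, every once-mentioned digit-free name would be discarded,
  which contradicts observed per-class recall for trivial names.
* **scope**: "the same piece of text" defaults to the whole document, since
  the corpus unit is an abstract; a naive sentence scope (splitting at
  `.!?` before whitespace) is available but intentionally simple — sentence
  segmentation is not this package's contribution.
* "Long-form names" are not defined in the modelled procedure; here they
  are active terms with at least two tokens or at least `min_length`
  characters that are not short-form rewrites. Keyword candidacy excludes
  the matcher's ignored tokens: in small dictionaries "of" or "and" would
  fall below any sensible frequency threshold and every document would
  trivially evidence every concept.

## Evaluation

A prediction is a true positive only when its span equals a gold span
exactly (per document; duplicate spans collapse first — multiplicity at one
span is not defined by exact-boundary scoring, so we collapse rather than
guess). Predictions in documents absent from the gold set count as false
positives, because corpora legitimately include abstracts with no entities.
Precision = TP/(TP+FP), Recall = TP/(TP+FN), F = 2PR/(P+R), with zero
denominators reported as 0. Reported tables round half-up to two decimals.
Per-class recall is computed over each class's gold subset, with absent
classes undefined (`NA`).

False negatives are auto-categorized by the first applicable rule:
`partial_match` (a kept prediction overlaps without boundary equality, the
dominant error source for long chemical names), `removed_by_disambiguation`,
`removed_by_stoplist`, `tokenization_error` (the surface is an active term
verbatim yet produced no exact match), `not_in_dictionary`, else
`manual_review`. False positives are labelled `partial_match` or
`manual_review` only — distinguishing annotation errors, out-of-scope
entities and non-chemicals requires human judgment, so the package flags
rather than guesses.

## The synthetic fixture generator

Real curated chemical dictionaries are licensed and large; the package
therefore ships seeded generators whose outputs are fully manifest-backed,
so the generator itself is the oracle for every downstream stage. Names are
pronounceable synthetic stems (not real chemistry, by design — this avoids
redistributing any licensed lexicon and keeps every planted property
exact). Concept classes follow the class mix of the reference annotated
corpus (391 IUPAC, 92 PART, 49 SUM, 414 TRIV, 161 ABB, 99 FAM occurrences,
used as proportions), with class-typical shapes: locant multiword names for
IUPAC, sum-formula strings, single-word trivial/family names, and
long-form/abbreviation pairs whose short form is co-mentioned with its long
form in documents (synonym evidence). At configurable rates the generator
plants: evidence-free short synonyms that occur in text as ordinary words
(homonym traps — disambiguation must remove exactly these), dosage-bearing
synonyms occurring in text (removed by filtering), common-English-word
synonyms occurring in text (removed by the reviewed stoplist; the
`common_term_rate` field exists so the frequent-terms stage has planted
work to do), invertible/possessive/splittable synonyms for the rewrite
rules, and partial-name traps where gold annotates a longer name embedding
a dictionary term. Trap concepts are restricted to classes whose base-name
tokens are globally unique and receive no other planted synonyms; otherwise
shared tokens like "acid" could leak keyword evidence into a trap document
and the removed-exactly-the-traps property would not be decidable from the
manifest. About one document in ten carries no entities, matching how such
corpora are assembled.

What the fixtures do **not** emulate: real nomenclature morphology,
MEDLINE-scale ambiguity, spelling variation, and annotation noise.
Consequently a perfect score on the trap-free corpus validates the
machinery (tokenizer, index, largest match, span bookkeeping), not
performance on real text, where dictionary coverage dominates recall and
partial matches dominate the false positives.

## Default parameters and problem sizes

| Parameter | Default | Meaning |
|---|---|---|
| ignored tokens | of, the, and, in | deleted from index keys, skipped in matching |
| stop words (rule 1) | of, the, and, in | removed before the single-token test |
| `roman_max` | 3999 | largest roman numeral removed by rule 1 |
| `top_n` | 500 | frequent-term candidates proposed for review |
| `min_length` | 5 chars | potential-homonym length threshold |
| `keyword_threshold` | 1000 | dictionary-wide count below which a token is a keyword |
| `fixture_spec()` rates | 0.15 / 0.1 / 0.1 / 0.2 / 0.1 | trap / partial / feature / rewriteable / common-word fractions |
| fixture size | 40 concepts, 25 documents | default synthetic study size |

The packaged test suite runs the matcher against a brute-force all-window
oracle on 200+ random instances of up to ~60 tokens and 12 terms, and
concept merging against a transitive-closure oracle on dictionaries of up
to 50 concepts; synthetic end-to-end runs use the 40-concept/25-document
default. These sizes make every property exhaustively checkable while
keeping the whole suite fast; they are package choices, and all generators
scale to larger sizes by changing `fixture_spec()`.

## Known limitations

* Recall on real corpora is bounded by dictionary coverage; nothing in the
  package invents names (no fuzzy matching, no word-order-insensitive
  matching — the modelled system runs word-order sensitive).
* Chemical-name boundary detection (which would address partial matches) is
  out of scope; partial matches are measured and categorized, not fixed.
* The SKOS reader is deliberately minimal: `skos:Concept`,
  `skos:prefLabel`, `skos:altLabel` and typed `skos:notation` only.
* FP error categories beyond partial matches require human judgment and are
  reported as `manual_review`.
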