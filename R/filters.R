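default_feature_patterns <- function() {
  # first match (in this order) names the logged feature
  c(
    dosage = paste0("(?i)\\b[0-9]+(?:\\.[0-9]+)?(?:\\s*-\\s*[0-9]+(?:\\.[0-9]+)?)?",
                    "\\s*(?:%|percent\\b|grams?\\b|g\\b|micrograms?\\b|mcg\\b|",
                    "\u00b5g|ug\\b|ml\\b|milliliters?\\b)"),
    not_otherwise_specified = "(?i)\\bnot otherwise specified\\b",
    not_specified = "(?i)\\bnot specified\\b",
    unspecified = "(?i)\\bunspecified\\b",
    nos_after_comma = "(?i),\\s*nos\\s*$",
    nos_bracketed = "(?i)\\s[\\(\\[]nos[\\)\\]]\\s*$",
    other_at_boundary = "(?i)(?:^other\\s|\\sother$)",
    deprecated = "(?i)\\bdeprecated\\b",
    unknown = "(?i)\\bunknown\\b",
    obsolete = "(?i)\\bobsolete\\b",
    miscellaneous = "(?i)\\bmiscellaneous\\b",
    no_prefix = "(?i)^no\\s"
  )
}

#' Term-filter configuration
#'
#' Removal rules operate on dictionary terms:
#' \enumerate{
#'   \item a term is removed when, after tokenization and stop-word removal,
#'     a single token remains that is one character long, an arabic integer,
#'     or a roman numeral (e.g. "T" as an abbreviation for tritium);
#'   \item a term is removed when it carries a suppression feature: a dosage
#'     in percent/gram/microgram/milliliter, "not otherwise specified",
#'     "not specified" or "unspecified", "NOS" at the end after a comma or
#'     space-preceded in brackets, "other" at a term boundary, "deprecated",
#'     "unknown", "obsolete", "miscellaneous", or leading "no ";
#'   \item a term is removed when its lower-cased surface is on the reviewed
#'     stoplist (built from the most frequent matched terms in a reference
#'     corpus; see [frequent_term_candidates()]).
#' }
#'
#' @param stopwords tokens ignored when deciding rule 1.
#' @param feature_patterns ordered named PCRE patterns for rule 2; the first
#'   matching pattern's name is logged.
#' @param roman_max largest roman-numeral value rule 1 recognizes.
#' @param roman_allowlist surfaces never treated as roman numerals (escape
#'   hatch for drug codes that happen to be valid numerals).
#' @param stoplist lower-cased term surfaces removed by rule 3.
#' @param top_n how many frequent-term candidates to propose for review.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(stopwords = c("of", "the", "and", "in"),
                          feature_patterns = default_feature_patterns(),
                          roman_max = 3999,
                          roman_allowlist = character(),
                          stoplist = character(),
                          top_n = 500) {
  stopifnot(top_n >= 1, roman_max >= 1)
  structure(
    list(stopwords = tolower(stopwords),
         feature_patterns = feature_patterns,
         roman_max = roman_max,
         roman_allowlist = tolower(roman_allowlist),
         stoplist = tolower(stoplist),
         top_n = top_n),
    class = "filter_config"
  )
}

ROMAN_PATTERN <- "^(M{0,3})(CM|CD|D?C{0,3})(XC|XL|L?X{0,3})(IX|IV|V?I{0,3})$"

roman_value <- function(s) {
  s <- toupper(s)
  vals <- c(I = 1, V = 5, X = 10, L = 50, C = 100, D = 500, M = 1000)
  v <- vals[strsplit(s, "", fixed = TRUE)[[1]]]
  if (length(v) == 0L || anyNA(v)) return(NA_real_)
  total <- 0
  for (i in seq_along(v)) {
    total <- total + if (i < length(v) && v[i] < v[i + 1]) -v[i] else v[i]
  }
  total
}

is_roman_numeral <- function(s, cfg) {
  s <- toupper(s)
  if (!nzchar(s) || tolower(s) %in% cfg$roman_allowlist) return(FALSE)
  if (!grepl(ROMAN_PATTERN, s)) return(FALSE)
  v <- roman_value(s)
  !is.na(v) && v >= 1 && v <= cfg$roman_max
}

#' Removal rule 1: single trivial token
#'
#' TRUE when the whole term, after tokenization and deletion of stop-word
#' tokens, is a single token that is one character long, an arabic integer,
#' or a roman numeral (strict subtractive notation, case-insensitive).
#'
#' @param term term surface.
#' @param cfg a [filter_config()].
#' @param tok_cfg a [tokenizer_config()].
#' @return logical with attribute `detail` (`"single_character"`,
#'   `"arabic_number"`, `"roman_numeral"`, or `NA`).
#' @export
is_single_trivial <- function(term, cfg = filter_config(),
                              tok_cfg = tokenizer_config()) {
  toks <- tokenize(term, tok_cfg)
  norm <- toks$normalized[nzchar(toks$normalized)]
  norm <- norm[!norm %in% cfg$stopwords]
  detail <- NA_character_
  res <- FALSE
  if (length(norm) == 1L) {
    t1 <- norm[1]
    if (nchar(t1) == 1L) {
      res <- TRUE; detail <- "single_character"
    } else if (grepl("^[0-9]+$", t1)) {
      res <- TRUE; detail <- "arabic_number"
    } else if (is_roman_numeral(t1, cfg)) {
      res <- TRUE; detail <- "roman_numeral"
    }
  }
  structure(res, detail = detail)
}

#' Removal rule 2: suppression features
#'
#' Scans the term for suppression features in the configured pattern order
#' (dosage, "not otherwise specified", "not specified", "unspecified",
#' terminal "NOS" after a comma or bracketed after a space, boundary "other",
#' "deprecated", "unknown", "obsolete", "miscellaneous", leading "no ").
#' Matching is case-insensitive and position-anchored where the rule demands
#' it, so "noscapine" is untouched while "insulin, NOS" is flagged.
#'
#' @param term term surface.
#' @param cfg a [filter_config()].
#' @return the name of the first matching feature, or `NA_character_`.
#' @export
has_suppression_feature <- function(term, cfg = filter_config()) {
  for (nm in names(cfg$feature_patterns)) {
    if (grepl(cfg$feature_patterns[[nm]], term, perl = TRUE)) return(nm)
  }
  NA_character_
}

#' Apply removal rules to a dictionary
#'
#' Marks active terms failing rule 1 (single trivial token), rule 2
#' (suppression feature) or rule 3 (stoplist membership) as
#' `status = "removed"` with the corresponding `removal_reason`; terms are
#' never deleted. Idempotent: removed terms are not re-examined.
#'
#' @param d a [chem_dictionary()].
#' @param cfg a [filter_config()].
#' @param tok_cfg a [tokenizer_config()].
#' @return list with `dictionary` (updated) and `log` (data.frame
#'   `concept_id`, `surface`, `rule`, `detail`; one row per removed term).
#' @export
apply_removal_rules <- function(d, cfg = filter_config(),
                                tok_cfg = tokenizer_config()) {
  validate_dictionary(d)
  terms <- d$terms
  log_rows <- list()
  for (i in which(terms$status == "active")) {
    surf <- terms$surface[i]
    rule <- NA_character_
    detail <- NA_character_
    r1 <- is_single_trivial(surf, cfg, tok_cfg)
    if (isTRUE(as.logical(r1))) {
      rule <- "single_trivial"; detail <- attr(r1, "detail")
    } else {
      f <- has_suppression_feature(surf, cfg)
      if (!is.na(f)) {
        rule <- "feature"; detail <- f
      } else if (tolower(surf) %in% cfg$stoplist) {
        rule <- "stoplist"; detail <- "stoplist"
      }
    }
    if (!is.na(rule)) {
      terms$status[i] <- "removed"
      terms$removal_reason[i] <- rule
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        concept_id = terms$concept_id[i], surface = surf,
        rule = rule, detail = detail, stringsAsFactors = FALSE
      )
    }
  }
  d$terms <- terms
  log <- if (length(log_rows)) do.call(rbind, log_rows) else {
    empty_df(concept_id = "character", surface = "character",
             rule = "character", detail = "character")
  }
  list(dictionary = d, log = log)
}

# split on ", " at bracket depth zero
toplevel_comma_split <- function(term) {
  ch <- strsplit(term, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] %in% BRACKET_OPEN) depth <- depth + 1L
    if (ch[i] %in% BRACKET_CLOSE) depth <- depth - 1L
    if (depth == 0L && ch[i] == "," && i < length(ch) && ch[i + 1] == " ") {
      cuts <- c(cuts, i)
    }
  }
  if (!length(cuts)) return(NULL)
  bounds <- c(0L, cuts, length(ch) + 1L)
  segs <- character(length(cuts) + 1L)
  for (k in seq_along(segs)) {
    from <- bounds[k] + if (k == 1L) 1L else 2L # skip ", "
    segs[k] <- trimws(paste(ch[from:(bounds[k + 1L] - 1L)], collapse = ""))
  }
  segs
}

#' Rewrite rule 1: syntactic inversion
#'
#' Rewrites comma-inverted lexicon forms into natural order: segments split
#' at top-level ", " are re-ordered last-to-first, so
#' "acid, gamma-vinyl-gamma-aminobutyric" becomes
#' "gamma-vinyl-gamma-aminobutyric acid". Commas inside brackets do not
#' split.
#'
#' @param term term surface.
#' @return the rewritten term, or `NULL` when the term has no top-level
#'   comma.
#' @export
syntactic_inversion <- function(term) {
  segs <- toplevel_comma_split(term)
  if (is.null(segs) || any(!nzchar(segs))) return(NULL)
  paste(rev(segs), collapse = " ")
}

#' Rewrite rule 2: possessive stripping
#'
#' Removes every "'s" occurring at a word end ("Ringer's lactate" to
#' "Ringer lactate").
#'
#' @param term term surface.
#' @return the stripped term, or `NULL` when nothing changed.
#' @export
strip_possessive <- function(term) {
  out <- gsub("'s(?![[:alnum:]])", "", term, perl = TRUE)
  if (identical(out, term)) NULL else out
}

#' Rewrite rule 3: long/short-form splitting
#'
#' Splits terms ending in a parenthesised token into the long form and the
#' short form: "Hydrogen chloride (HCL)" yields "Hydrogen chloride" and
#' "HCL". A bare parenthesised term ("(HCL)") is left alone.
#'
#' @param term term surface.
#' @return character vector `c(long, short)`, or `NULL`.
#' @export
split_long_short_form <- function(term) {
  m <- regexec("^(.*[^ ]) *\\(([^()]+)\\) *$", term)[[1]]
  if (m[1] == -1L) return(NULL)
  parts <- regmatches(term, list(m))[[1]]
  long <- trimws(parts[2])
  short <- trimws(parts[3])
  if (!nzchar(long) || !nzchar(short)) return(NULL)
  c(long, short)
}

#' Apply rewrite rules to a dictionary
#'
#' For every active source term, adds the syntactic inversion, the stripped
#' possessive, and the long/short forms where applicable, each tagged with
#' its origin. Originals are always retained, case-insensitive duplicates
#' within a concept are not added, and rewrites are not chained (a split
#' product is never inverted), so applying the rules twice adds nothing.
#'
#' @param d a [chem_dictionary()].
#' @return list with `dictionary`, `n_added`, and `log` (data.frame
#'   `concept_id`, `source_surface`, `new_surface`, `origin`).
#' @export
apply_rewrite_rules <- function(d) {
  validate_dictionary(d)
  log_rows <- list()
  new_rows <- list()
  for (cid in d$concepts$concept_id) {
    idx <- which(d$terms$concept_id == cid)
    have <- tolower(d$terms$surface[idx])
    src <- idx[d$terms$status[idx] == "active" & d$terms$origin[idx] == "source"]
    for (i in src) {
      surf <- d$terms$surface[i]
      cand <- list()
      inv <- syntactic_inversion(surf)
      if (!is.null(inv)) cand[[length(cand) + 1L]] <- c(inv, "inversion")
      pos <- strip_possessive(surf)
      if (!is.null(pos)) cand[[length(cand) + 1L]] <- c(pos, "possessive")
      ls <- split_long_short_form(surf)
      if (!is.null(ls)) {
        cand[[length(cand) + 1L]] <- c(ls[1], "longform")
        cand[[length(cand) + 1L]] <- c(ls[2], "shortform")
      }
      for (cc in cand) {
        if (tolower(cc[1]) %in% have) next
        have <- c(have, tolower(cc[1]))
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          concept_id = cid, surface = cc[1], preferred = FALSE,
          origin = cc[2], status = "active", removal_reason = NA_character_,
          stringsAsFactors = FALSE
        )
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          concept_id = cid, source_surface = surf, new_surface = cc[1],
          origin = cc[2], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(new_rows)) {
    d$terms <- rbind(d$terms, do.call(rbind, new_rows))
    rownames(d$terms) <- NULL
  }
  validate_dictionary(d)
  log <- if (length(log_rows)) do.call(rbind, log_rows) else {
    empty_df(concept_id = "character", source_surface = "character",
             new_surface = "character", origin = "character")
  }
  list(dictionary = d, n_added = length(new_rows), log = log)
}

#' Frequent-term candidates for stoplist review
#'
#' Indexes a document set with the dictionary and ranks matched terms by raw
#' occurrence count (ties broken lexicographically). The output is meant for
#' human review: terms judged to be general English go on the rule-3
#' stoplist.
#'
#' @param d a [chem_dictionary()].
#' @param corpus named character vector of document texts.
#' @param top_n number of candidates to return.
#' @param tok_cfg a [tokenizer_config()].
#' @param ignored non-informative tokens skipped by the matcher.
#' @return data.frame (`term`, `count`) sorted by decreasing count.
#' @export
frequent_term_candidates <- function(d, corpus, top_n = 500,
                                     tok_cfg = tokenizer_config(),
                                     ignored = c("of", "the", "and", "in")) {
  if (!length(corpus)) {
    return(empty_df(term = "character", count = "integer"))
  }
  idx <- build_index(d, tok_cfg, ignored)
  counts <- new.env(parent = emptyenv())
  doc_ids <- names(corpus) %||% as.character(seq_along(corpus))
  for (k in seq_along(corpus)) {
    ann <- find_matches(corpus[[k]], idx, doc_id = doc_ids[k])
    for (term in tolower(ann$matched_term)) {
      counts[[term]] <- (counts[[term]] %||% 0L) + 1L
    }
  }
  terms <- ls(counts)
  if (!length(terms)) return(empty_df(term = "character", count = "integer"))
  out <- data.frame(term = terms,
                    count = vapply(terms, function(t) counts[[t]], 0L),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
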