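#' Disambiguation configuration
#'
#' Controls the homonym rules. A term is a \emph{dictionary homonym} when it
#' refers to more than one concept; a dictionary homonym that is the
#' preferred term of a concept is handled as unambiguous for that concept.
#' Dictionary-unique terms are still \emph{potential homonyms} when they are
#' shorter than `min_length` characters or (depending on `digit_rule`) do not
#' contain a number. (Potential) homonyms are only kept with contextual
#' evidence: a co-occurring synonym of the same concept, or a concept keyword
#' in the same piece of text.
#'
#' @param min_length character-length threshold below which a term is a
#'   potential homonym (default 5).
#' @param digit_rule `"or"` (short OR lacking a digit triggers potential
#'   homonymy — the literal reading) or `"and"` (both required — a stricter
#'   variant that leaves most trivial names unambiguous).
#' @param self_evidence logical; when `TRUE` (default) a mention's own tokens
#'   may satisfy the keyword condition. Without this, every long trivial name
#'   lacking digits would be discarded in documents that mention it only
#'   once, which contradicts the recall dictionary-based taggers actually
#'   achieve on trivial names.
#' @param scope evidence scope: `"document"` (default; corpus documents are
#'   abstracts) or `"sentence"` (naive sentence splitting on `.`/`!`/`?`).
#' @param keyword_threshold a token is a keyword candidate only when it
#'   occurs fewer than this many times in the whole dictionary (default
#'   1000).
#' @return an object of class `disambiguation_config`.
#' @export
disambiguation_config <- function(min_length = 5,
                                  digit_rule = c("or", "and"),
                                  self_evidence = TRUE,
                                  scope = c("document", "sentence"),
                                  keyword_threshold = 1000) {
  stopifnot(min_length >= 1, keyword_threshold >= 1)
  structure(
    list(min_length = min_length,
         digit_rule = match.arg(digit_rule),
         self_evidence = isTRUE(self_evidence),
         scope = match.arg(scope),
         keyword_threshold = keyword_threshold),
    class = "disambiguation_config"
  )
}

# map: normalized term key -> concept ids carrying it (active terms only)
key_concept_map <- function(d, tok_cfg, ignored) {
  at <- active_terms(d)
  keys <- vapply(at$surface, term_key, "", tok_cfg = tok_cfg, ignored = ignored)
  list(at = at, keys = keys)
}

#' Classify a term's ambiguity
#'
#' @param term an active term surface of `concept_id`.
#' @param concept_id the concept the term is being read as.
#' @param d a [chem_dictionary()].
#' @param cfg a [disambiguation_config()].
#' @param tok_cfg a [tokenizer_config()].
#' @param ignored matcher ignore list (key comparison must match the index).
#' @return one of `"unambiguous"`, `"dictionary_homonym"`,
#'   `"preferred_exception"`, `"potential_homonym"`.
#' @export
classify_ambiguity <- function(term, concept_id, d,
                               cfg = disambiguation_config(),
                               tok_cfg = tokenizer_config(),
                               ignored = c("of", "the", "and", "in")) {
  km <- key_concept_map(d, tok_cfg, ignored)
  key <- term_key(term, tok_cfg, ignored)
  carriers <- unique(km$at$concept_id[km$keys == key])
  if (!concept_id %in% carriers) {
    stop("'", term, "' is not an active term of concept ", concept_id)
  }
  classify_ambiguity_impl(term, key, concept_id, carriers, km, cfg)
}

classify_ambiguity_impl <- function(term, key, concept_id, carriers, km, cfg) {
  if (length(carriers) >= 2L) {
    pref_key <- km$keys[km$at$concept_id == concept_id & km$at$preferred]
    if (length(pref_key) && pref_key[1] == key) return("preferred_exception")
    return("dictionary_homonym")
  }
  short <- nchar(term) < cfg$min_length
  no_digit <- !grepl("[0-9]", term)
  potential <- if (cfg$digit_rule == "or") short || no_digit else short && no_digit
  if (potential) "potential_homonym" else "unambiguous"
}

#' Build the dictionary-wide keyword table
#'
#' Counts each normalized token's occurrences across all active term
#' surfaces (every occurrence in every term counts). A concept's keywords are
#' the tokens of its long-form names — terms with at least two tokens or at
#' least `min_length` characters that are not short-form rewrites — whose
#' dictionary-wide count falls below the threshold. Tokens on the matcher's
#' ignore list are never keywords.
#'
#' @param d a [chem_dictionary()].
#' @param cfg a [disambiguation_config()].
#' @param tok_cfg a [tokenizer_config()].
#' @param ignored matcher ignore list.
#' @return an object of class `keyword_table`: list with `counts` (named
#'   integer vector) and `threshold`.
#' @export
build_keyword_table <- function(d, cfg = disambiguation_config(),
                                tok_cfg = tokenizer_config(),
                                ignored = c("of", "the", "and", "in")) {
  at <- active_terms(d)
  all_tokens <- unlist(lapply(at$surface, function(s) {
    toks <- tokenize(s, tok_cfg)
    toks$normalized[nzchar(toks$normalized)]
  }))
  counts <- table(all_tokens)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[!names(counts) %in% ignored]
  structure(list(counts = counts, threshold = cfg$keyword_threshold),
            class = "keyword_table")
}

#' @export
print.keyword_table <- function(x, ...) {
  cat("<keyword_table> ", length(x$counts), " tokens, threshold ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

#' Export a keyword table as TSV
#' @param kt a [build_keyword_table()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_keyword_table <- function(kt, path) {
  out <- data.frame(token = names(kt$counts), count = unname(kt$counts))
  out <- out[order(out$token), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# keywords of one concept (normalized tokens of its long-form names that are
# rare dictionary-wide)
concept_keywords <- function(d, concept_id, kt, cfg, tok_cfg, ignored) {
  at <- active_terms(d)
  at <- at[at$concept_id == concept_id & at$origin != "shortform", , drop = FALSE]
  kws <- character()
  for (s in at$surface) {
    toks <- tokenize(s, tok_cfg)
    norm <- toks$normalized[nzchar(toks$normalized)]
    if (length(norm) >= 2L || nchar(s) >= cfg$min_length) {
      kws <- c(kws, norm)
    }
  }
  kws <- setdiff(unique(kws), ignored)
  kws[kws %in% names(kt$counts) & kt$counts[kws] < kt$threshold]
}

# naive sentence segmentation: returns the sentence index of each character
sentence_index_at <- function(doc, positions) {
  ends <- gregexpr("[.!?]+(\\s|$)", doc, perl = TRUE)[[1]]
  if (ends[1] == -1L) return(rep(1L, length(positions)))
  bound <- as.integer(ends) + attr(ends, "match.length") - 1L # 1-based end
  findInterval(positions, bound, left.open = FALSE) + 1L
}

#' Apply disambiguation rules to annotations
#'
#' Mentions of unambiguous terms and preferred-term exceptions are kept.
#' (Potential) homonym mentions are kept only when (1) a different term of
#' the same concept is also annotated in the same piece of text, or (2) a
#' keyword of the concept occurs among the text's normalized tokens. Kept
#' dictionary homonyms resolve their `concept_ids` to the evidenced
#' concept(s). Rejected mentions are flagged `removed_by_disambiguation`,
#' never deleted. The decision for each mention depends only on the document
#' and the full input annotation set, so processing order is irrelevant.
#'
#' @param annotations matcher output ([tag_corpus()] / [find_matches()]).
#' @param docs named character vector of the same documents.
#' @param d the dictionary the index was built from.
#' @param kt a [build_keyword_table()] result (built from `d` if omitted).
#' @param cfg a [disambiguation_config()].
#' @param tok_cfg a [tokenizer_config()].
#' @param ignored matcher ignore list.
#' @return the annotations with `status`, `ambiguity` and `evidence` columns
#'   set.
#' @export
disambiguate <- function(annotations, docs, d, kt = NULL,
                         cfg = disambiguation_config(),
                         tok_cfg = tokenizer_config(),
                         ignored = c("of", "the", "and", "in")) {
  if (is.null(kt)) kt <- build_keyword_table(d, cfg, tok_cfg, ignored)
  ann <- annotations
  ann$ambiguity <- NA_character_
  ann$evidence <- NA_character_
  if (!nrow(ann)) return(ann)
  km <- key_concept_map(d, tok_cfg, ignored)
  carriers_of <- function(key) unique(km$at$concept_id[km$keys == key])
  kw_cache <- new.env(parent = emptyenv())
  keywords_of <- function(cid) {
    if (is.null(kw_cache[[cid]])) {
      kw_cache[[cid]] <- concept_keywords(d, cid, kt, cfg, tok_cfg, ignored)
    }
    kw_cache[[cid]]
  }
  doc_ids <- names(docs) %||% as.character(seq_along(docs))
  for (doc_id in unique(ann$doc_id)) {
    doc <- docs[[match(doc_id, doc_ids)]]
    toks <- tokenize(doc, tok_cfg)
    toks <- toks[nzchar(toks$normalized), , drop = FALSE]
    if (cfg$scope == "sentence") {
      tok_sent <- sentence_index_at(doc, toks$start + 1L)
    } else {
      tok_sent <- rep(1L, nrow(toks))
    }
    rows <- which(ann$doc_id == doc_id)
    ann_sent <- if (cfg$scope == "sentence") {
      sentence_index_at(doc, ann$start[rows] + 1L)
    } else rep(1L, length(rows))
    for (j in seq_along(rows)) {
      i <- rows[j]
      cids <- split_field(ann$concept_ids[i])
      classes <- character(length(cids))
      kept_cids <- character()
      ev <- character()
      for (k in seq_along(cids)) {
        cid <- cids[k]
        cls <- classify_ambiguity_impl(ann$matched_term[i], ann$key[i], cid,
                                       carriers_of(ann$key[i]), km, cfg)
        classes[k] <- cls
        if (cls %in% c("unambiguous", "preferred_exception")) {
          kept_cids <- c(kept_cids, cid)
          ev <- c(ev, if (cls == "unambiguous") "none_needed" else "preferred_term")
          next
        }
        # condition (1): a different term of the same concept in scope
        others <- setdiff(rows, i)
        syn <- others[vapply(others, function(o) {
          cid %in% split_field(ann$concept_ids[o]) && ann$key[o] != ann$key[i]
        }, TRUE)]
        if (cfg$scope == "sentence" && length(syn)) {
          syn <- syn[ann_sent[match(syn, rows)] == ann_sent[j]]
        }
        if (length(syn)) {
          kept_cids <- c(kept_cids, cid)
          ev <- c(ev, "synonym")
          next
        }
        # condition (2): a concept keyword among the text's tokens
        kws <- keywords_of(cid)
        if (length(kws)) {
          in_scope <- if (cfg$scope == "sentence") tok_sent == ann_sent[j] else rep(TRUE, nrow(toks))
          if (!cfg$self_evidence) {
            inside <- toks$start < ann$end[i] & toks$end > ann$start[i]
            in_scope <- in_scope & !inside
          }
          if (any(toks$normalized[in_scope] %in% kws)) {
            kept_cids <- c(kept_cids, cid)
            ev <- c(ev, "keyword")
            next
          }
        }
      }
      ann$ambiguity[i] <- paste(classes, collapse = ";")
      if (length(kept_cids)) {
        ann$status[i] <- "kept"
        ann$concept_ids[i] <- paste(sort(unique(kept_cids)), collapse = ";")
        ann$evidence[i] <- paste(unique(ev), collapse = ";")
      } else {
        ann$status[i] <- "removed_by_disambiguation"
        ann$evidence[i] <- "none"
      }
    }
  }
  ann
}
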