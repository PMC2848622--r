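SYLLABLES <- c("zor", "vex", "mab", "tol", "quen", "dex", "fen", "lor", "mex",
               "bal", "cur", "dov", "gal", "hax", "jin", "kol", "lum", "mig",
               "nup", "pix", "rud", "sev", "tib", "vun", "wex", "yam", "zel",
               "bor", "cav", "dru", "fim", "gos", "hul", "jec", "kam", "lep")

TRAP_WORDS <- c("tas", "bru", "vel", "mor", "pin", "sal", "gor", "nix", "dal",
                "rem", "fos", "keb", "lun", "paz", "rog")

COMMON_WORDS <- c("process", "control", "sample", "factor", "signal", "during",
                  "result", "system", "change", "effect")

PARTIAL_MODIFIERS <- c("ultra", "mega", "neo")

#' Fixture specification
#'
#' Describes a synthetic dictionary/corpus pair with planted, manifest-backed
#' structure. Names are pronounceable synthetic stems, not real chemistry:
#' every planted property (trap, feature term, rewritable form) is recorded
#' so downstream modules can be checked against an exact oracle.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_concepts number of concepts to generate.
#' @param class_mix named proportions over IUPAC/PART/SUM/TRIV/ABB/FAM;
#'   defaults follow the class frequencies of the reference annotated corpus
#'   (391/92/49/414/161/99 occurrences).
#' @param homonym_trap_rate fraction of concepts given a short, digit-free
#'   synonym that also occurs in text without contextual evidence (the
#'   "As"-for-arsenic situation).
#' @param partial_trap_rate fraction of concepts embedded in a longer
#'   non-dictionary name in text (gold annotates the long name; only the
#'   embedded term can match).
#' @param feature_term_rate fraction of concepts given a synonym carrying a
#'   suppression feature (a dosage), which also occurs in text as a non-gold
#'   string.
#' @param rewriteable_rate fraction of concepts given inverted, possessive
#'   and splittable synonyms for the rewrite rules to act on.
#' @param common_term_rate fraction of concepts given a common-English-word
#'   synonym planted in text; these words form the recommended stoplist and
#'   exercise the frequent-terms correction stage.
#' @param n_docs number of corpus documents (roughly one in ten carries no
#'   entities).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_concepts = 40L,
                         class_mix = c(IUPAC = 391, PART = 92, SUM = 49,
                                       TRIV = 414, ABB = 161, FAM = 99) / 1206,
                         homonym_trap_rate = 0.15,
                         partial_trap_rate = 0.1,
                         feature_term_rate = 0.1,
                         rewriteable_rate = 0.2,
                         common_term_rate = 0.1,
                         n_docs = 25L) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-9,
            setequal(names(class_mix), ENTITY_CLASSES),
            n_concepts >= 1, n_docs >= 1)
  rates <- c(homonym_trap_rate, partial_trap_rate, feature_term_rate,
             rewriteable_rate, common_term_rate)
  stopifnot(all(rates >= 0 & rates <= 1))
  structure(
    list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
         class_mix = class_mix,
         homonym_trap_rate = homonym_trap_rate,
         partial_trap_rate = partial_trap_rate,
         feature_term_rate = feature_term_rate,
         rewriteable_rate = rewriteable_rate,
         common_term_rate = common_term_rate,
         n_docs = as.integer(n_docs)),
    class = "fixture_spec"
  )
}

cap1 <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))

new_name_pool <- function() {
  used <- new.env(parent = emptyenv())
  list(
    stem = function() {
      repeat {
        s <- paste(sample(SYLLABLES, sample(2:3, 1), replace = TRUE), collapse = "")
        if (is.null(used[[s]])) {
          used[[s]] <- TRUE
          return(s)
        }
      }
    },
    claim = function(s) {
      key <- tolower(s)
      if (!is.null(used[[key]])) return(FALSE)
      used[[key]] <- TRUE
      TRUE
    }
  )
}

# 3-letter abbreviation avoiding roman-numeral letters
make_abbrev <- function(pool) {
  allowed <- setdiff(LETTERS, c("I", "V", "X", "L", "C", "D", "M"))
  repeat {
    a <- paste(sample(allowed, 3, replace = TRUE), collapse = "")
    if (pool$claim(a)) return(a)
  }
}

pick_subset <- function(n, rate) {
  k <- round(n * rate)
  if (k == 0L) integer(0) else sample.int(n, k)
}

#' Generate a synthetic dictionary
#'
#' Concepts get class-typical names (comma/locant multiword names for
#' IUPAC-like entries, sum-formula strings, single-word trivial and family
#' names, long-form/abbreviation pairs), unique CAS numbers, InChI strings
#' for every other concept, and — at the configured rates — planted trap,
#' feature, common-word and rewritable synonyms. The manifest records every
#' planted property.
#'
#' @param spec a [fixture_spec()].
#' @return an object of class `chem_fixture_dictionary`: list with
#'   `dictionary`, `manifest` and `spec`.
#' @export
generate_dictionary <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  n <- spec$n_concepts
  pool <- new_name_pool()
  classes <- sample(names(spec$class_mix), n, replace = TRUE,
                    prob = spec$class_mix)
  cids <- sprintf("C%03d", seq_len(n))
  term_rows <- list()
  concept_rows <- list()
  id_rows <- list()
  info <- data.frame(concept_id = cids, class = classes,
                     mention_term = NA_character_,
                     mention_class = classes,
                     evidence_term = NA_character_,
                     stringsAsFactors = FALSE)
  add_term <- function(cid, surface, preferred = FALSE) {
    term_rows[[length(term_rows) + 1L]] <<- data.frame(
      concept_id = cid, surface = surface, preferred = preferred,
      origin = "source", status = "active", removal_reason = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n)) {
    cid <- cids[i]
    cls <- classes[i]
    if (cls == "IUPAC") {
      loc <- sort(sample(1:9, 2))
      name <- sprintf("%d,%d-di%syl %sane", loc[1], loc[2], pool$stem(), pool$stem())
      pool$claim(name)
      add_term(cid, name, preferred = TRUE)
      info$mention_term[i] <- name
    } else if (cls == "TRIV") {
      name <- sprintf("%sine", pool$stem())
      pool$claim(name)
      add_term(cid, name, preferred = TRUE)
      info$mention_term[i] <- name
    } else if (cls == "SUM") {
      repeat {
        name <- sprintf("C%dH%dN%d", sample(6:30, 1), sample(4:40, 1), sample(1:6, 1))
        if (pool$claim(name)) break
      }
      add_term(cid, name, preferred = TRUE)
      info$mention_term[i] <- name
    } else if (cls == "ABB") {
      long <- sprintf("%sic acid", pool$stem())
      pool$claim(long)
      short <- make_abbrev(pool)
      add_term(cid, long, preferred = TRUE)
      add_term(cid, short)
      info$mention_term[i] <- short
      info$evidence_term[i] <- long
    } else if (cls == "FAM") {
      name <- sprintf("%sanes", pool$stem())
      pool$claim(name)
      add_term(cid, name, preferred = TRUE)
      info$mention_term[i] <- name
    } else { # PART: a multiword fragment-style name
      name <- sprintf("%syl ester", pool$stem())
      pool$claim(name)
      add_term(cid, name, preferred = TRUE)
      info$mention_term[i] <- name
    }
    id_rows[[length(id_rows) + 1L]] <- data.frame(
      concept_id = cid, kind = "CAS",
      value = sprintf("%d-%02d-%d", 10000L + i, (i * 7L) %% 90L + 10L, i %% 10L),
      stringsAsFactors = FALSE
    )
    if (i %% 2L == 0L) {
      id_rows[[length(id_rows) + 1L]] <- data.frame(
        concept_id = cid, kind = "InChI",
        value = sprintf("InChI=1S/C%dH%d/s%d", i + 5L, i + 8L, i),
        stringsAsFactors = FALSE
      )
    }
    concept_rows[[i]] <- data.frame(
      concept_id = cid,
      formula = if (i %% 3L == 0L) sprintf("C%dH%dN%dO%d", i + 4L, i + 6L,
                                           i %% 4L + 1L, i %% 5L + 1L) else NA_character_,
      sources = "synthetic", stringsAsFactors = FALSE
    )
  }
  planted <- function(idx, make_row) {
    if (!length(idx)) {
      return(empty_df(concept_id = "character", surface = "character",
                      extra = "character"))
    }
    do.call(rbind, lapply(idx, make_row))
  }
  rw_idx <- pick_subset(n, spec$rewriteable_rate)
  invertible <- planted(rw_idx, function(i) {
    s <- pool$stem()
    surf <- sprintf("acid, %sic", s)
    add_term(cids[i], surf)
    data.frame(concept_id = cids[i], surface = surf,
               extra = sprintf("%sic acid", s), stringsAsFactors = FALSE)
  })
  possessive <- planted(rw_idx, function(i) {
    surf <- sprintf("%s's %sate", cap1(pool$stem()), pool$stem())
    add_term(cids[i], surf)
    data.frame(concept_id = cids[i], surface = surf,
               extra = gsub("'s", "", surf, fixed = TRUE), stringsAsFactors = FALSE)
  })
  splittable <- planted(rw_idx, function(i) {
    ab <- make_abbrev(pool)
    surf <- sprintf("%sol solution (%s)", cap1(pool$stem()), ab)
    add_term(cids[i], surf)
    data.frame(concept_id = cids[i], surface = surf, extra = ab,
               stringsAsFactors = FALSE)
  })
  feature_terms <- planted(pick_subset(n, spec$feature_term_rate), function(i) {
    surf <- sprintf("%sol 5%% solution", pool$stem())
    add_term(cids[i], surf)
    data.frame(concept_id = cids[i], surface = surf, extra = "dosage",
               stringsAsFactors = FALSE)
  })
  common_idx <- pick_subset(n, spec$common_term_rate)
  common_idx <- common_idx[seq_len(min(length(common_idx), length(COMMON_WORDS)))]
  common_words <- if (length(common_idx)) {
    sample(COMMON_WORDS, length(common_idx))
  } else character(0)
  common_terms <- planted(common_idx, function(i) {
    w <- common_words[match(i, common_idx)]
    add_term(cids[i], w)
    data.frame(concept_id = cids[i], surface = w, extra = "common",
               stringsAsFactors = FALSE)
  })
  # trap concepts: only classes whose base-name tokens are globally unique
  # (no shared "acid"/"ester" tokens that could leak keyword evidence into a
  # trap document), and no other planted synonyms
  trap_pool_idx <- setdiff(which(classes %in% c("IUPAC", "TRIV", "SUM")),
                           c(rw_idx, common_idx,
                             which(cids %in% feature_terms$concept_id)))
  n_traps <- min(round(n * spec$homonym_trap_rate), length(trap_pool_idx),
                 length(TRAP_WORDS))
  trap_idx <- if (n_traps > 0L) {
    sample(trap_pool_idx, n_traps)
  } else integer(0)
  trap_words <- if (length(trap_idx)) {
    sample(TRAP_WORDS, length(trap_idx))
  } else character(0)
  traps <- planted(trap_idx, function(i) {
    w <- trap_words[match(i, trap_idx)]
    add_term(cids[i], w)
    data.frame(concept_id = cids[i], surface = w, extra = "trap",
               stringsAsFactors = FALSE)
  })
  d <- chem_dictionary(
    do.call(rbind, term_rows),
    do.call(rbind, id_rows),
    do.call(rbind, concept_rows),
    provenance = sprintf("synthetic fixture (seed %d)", spec$seed)
  )
  manifest <- list(
    concepts = info,
    invertible = invertible, possessive = possessive, splittable = splittable,
    feature_terms = feature_terms, common_terms = common_terms, traps = traps,
    stoplist = sort(common_terms$surface),
    partial_candidates = setdiff(info$concept_id[info$class %in% c("TRIV", "FAM")],
                                 traps$concept_id)
  )
  structure(list(dictionary = d, manifest = manifest, spec = spec),
            class = "chem_fixture_dictionary")
}

FILLER_WORDS <- c("we", "observed", "that", "treatment", "with", "increased",
                  "the", "levels", "of", "and", "in", "a", "dose", "dependent",
                  "manner", "results", "were", "consistent", "across",
                  "replicates", "cells", "showed", "reduced", "growth",
                  "after", "exposure", "to", "this", "compound", "relative",
                  "controls", "measured", "by", "standard", "assays")

#' Generate a synthetic annotated corpus
#'
#' Template sentences embed dictionary terms as gold mentions with exact
#' spans. Abbreviation mentions are accompanied by a gold mention of their
#' long form in the same document (synonym evidence for disambiguation).
#' At the spec's rates the corpus also carries: evidence-free occurrences of
#' the planted homonym-trap synonyms (not gold — they should be removed by
#' disambiguation), occurrences of feature-carrying and common-word synonyms
#' (not gold — they should be removed by term filtering and the stoplist),
#' and partial-name traps where the gold span is a longer name embedding a
#' dictionary term. Roughly one document in ten carries no entities.
#'
#' @param fx a [generate_dictionary()] result.
#' @param spec a [fixture_spec()]; defaults to the one used for `fx`.
#' @return an object of class `chem_fixture_corpus`: list with `docs` (named
#'   character), `gold` (annotation data.frame) and `manifest` (planted
#'   trap/feature/common/partial occurrence tables).
#' @export
generate_corpus <- function(fx, spec = fx$spec) {
  stopifnot(inherits(fx, "chem_fixture_dictionary"))
  set.seed(spec$seed + 1L)
  info <- fx$manifest$concepts
  n_docs <- spec$n_docs
  doc_ids <- sprintf("doc%03d", seq_len(n_docs))
  n_zero <- if (n_docs >= 5L) max(1L, round(0.1 * n_docs)) else 0L
  zero_docs <- if (n_zero) sort(sample(doc_ids, n_zero)) else character(0)
  gold <- list()
  trap_rows <- list()
  feature_rows <- list()
  common_rows <- list()
  partial_rows <- list()
  texts <- stats::setNames(character(n_docs), doc_ids)
  doc_concepts <- stats::setNames(vector("list", n_docs), doc_ids)

  # per-document assembly state
  cur_text <- ""
  filler <- function(k) sample(FILLER_WORDS, k, replace = TRUE)
  append_words <- function(words, record_at = integer(0)) {
    spans <- list()
    for (j in seq_along(words)) {
      sep <- if (nzchar(cur_text)) " " else ""
      start <- nchar(cur_text) + nchar(sep)
      cur_text <<- paste0(cur_text, sep, words[j])
      if (j %in% record_at) {
        spans[[length(spans) + 1L]] <- c(start, start + nchar(words[j]))
      }
    }
    cur_text <<- paste0(cur_text, ".")
    spans
  }
  mention_sentence <- function(mention) {
    words <- c("The", filler(2), "of", mention, filler(3))
    append_words(words, record_at = 5L)[[1]]
  }
  filler_sentence <- function() {
    invisible(append_words(filler(sample(5:8, 1))))
  }

  for (di in seq_len(n_docs)) {
    doc_id <- doc_ids[di]
    cur_text <- ""
    if (doc_id %in% zero_docs) {
      for (s in seq_len(sample(2:4, 1))) filler_sentence()
      texts[[doc_id]] <- cur_text
      doc_concepts[[doc_id]] <- character(0)
      next
    }
    k <- sample(2:3, 1)
    picked <- sample(info$concept_id, min(k, nrow(info)))
    filler_sentence()
    for (cid in picked) {
      row <- info[info$concept_id == cid, ]
      sp <- mention_sentence(row$mention_term)
      gold[[length(gold) + 1L]] <- data.frame(
        doc_id = doc_id, start = sp[1], end = sp[2],
        surface = row$mention_term, class = row$mention_class,
        stringsAsFactors = FALSE
      )
      if (!is.na(row$evidence_term)) {
        sp2 <- mention_sentence(row$evidence_term)
        gold[[length(gold) + 1L]] <- data.frame(
          doc_id = doc_id, start = sp2[1], end = sp2[2],
          surface = row$evidence_term, class = "TRIV",
          stringsAsFactors = FALSE
        )
      }
    }
    filler_sentence()
    texts[[doc_id]] <- cur_text
    doc_concepts[[doc_id]] <- picked
  }

  entity_docs <- setdiff(doc_ids, zero_docs)
  insert_tail <- function(doc_id, words, record_at) {
    cur_text <<- texts[[doc_id]]
    spans <- append_words(words, record_at)
    texts[[doc_id]] <<- cur_text
    spans
  }
  # evidence-free trap occurrences: never in a document mentioning the
  # trap's own concept
  for (r in seq_len(nrow(fx$manifest$traps))) {
    tr <- fx$manifest$traps[r, ]
    ok <- entity_docs[vapply(entity_docs, function(dd) {
      !tr$concept_id %in% doc_concepts[[dd]]
    }, TRUE)]
    if (!length(ok)) next
    dd <- sample(ok, 1)
    sp <- insert_tail(dd, c("Moreover", filler(2), tr$surface, filler(2)), 4L)[[1]]
    trap_rows[[length(trap_rows) + 1L]] <- data.frame(
      doc_id = dd, start = sp[1], end = sp[2], surface = tr$surface,
      concept_id = tr$concept_id, stringsAsFactors = FALSE
    )
  }
  for (r in seq_len(nrow(fx$manifest$feature_terms))) {
    ft <- fx$manifest$feature_terms[r, ]
    dd <- sample(entity_docs, 1)
    sp <- insert_tail(dd, c("Doses", "of", ft$surface, filler(2)), 3L)[[1]]
    feature_rows[[length(feature_rows) + 1L]] <- data.frame(
      doc_id = dd, start = sp[1], end = sp[2], surface = ft$surface,
      concept_id = ft$concept_id, stringsAsFactors = FALSE
    )
  }
  for (r in seq_len(nrow(fx$manifest$common_terms))) {
    ct <- fx$manifest$common_terms[r, ]
    for (dd in sample(entity_docs, min(2L, length(entity_docs)))) {
      sp <- insert_tail(dd, c("Each", ct$surface, filler(3)), 2L)[[1]]
      common_rows[[length(common_rows) + 1L]] <- data.frame(
        doc_id = dd, start = sp[1], end = sp[2], surface = ct$surface,
        concept_id = ct$concept_id, stringsAsFactors = FALSE
      )
    }
  }
  # partial-name traps: gold annotates modifier + term; only the term matches
  part_pool <- fx$manifest$partial_candidates
  n_partial <- round(spec$n_concepts * spec$partial_trap_rate)
  part_pool <- part_pool[seq_len(min(n_partial, length(part_pool)))]
  for (cid in part_pool) {
    row <- info[info$concept_id == cid, ]
    long_name <- paste(sample(PARTIAL_MODIFIERS, 1), row$mention_term)
    dd <- sample(entity_docs, 1)
    sp <- insert_tail(dd, c("Derivatives", "such", "as", long_name, filler(2)), 4L)[[1]]
    gold[[length(gold) + 1L]] <- data.frame(
      doc_id = dd, start = sp[1], end = sp[2], surface = long_name,
      class = "PART", stringsAsFactors = FALSE
    )
    partial_rows[[length(partial_rows) + 1L]] <- data.frame(
      doc_id = dd, start = sp[1], end = sp[2], surface = long_name,
      concept_id = cid, embedded_term = row$mention_term,
      stringsAsFactors = FALSE
    )
  }

  bind <- function(rows, ...) {
    if (length(rows)) do.call(rbind, rows) else empty_df(...)
  }
  occ_cols <- list(doc_id = "character", start = "integer", end = "integer",
                   surface = "character", concept_id = "character")
  gold_df <- bind(gold, doc_id = "character", start = "integer",
                  end = "integer", surface = "character", class = "character")
  gold_df <- gold_df[order(gold_df$doc_id, gold_df$start), , drop = FALSE]
  rownames(gold_df) <- NULL
  structure(list(
    docs = texts,
    gold = gold_df,
    manifest = list(
      trap_mentions = do.call(bind, c(list(trap_rows), occ_cols)),
      feature_mentions = do.call(bind, c(list(feature_rows), occ_cols)),
      common_mentions = do.call(bind, c(list(common_rows), occ_cols)),
      partial_mentions = bind(partial_rows, doc_id = "character",
                              start = "integer", end = "integer",
                              surface = "character", concept_id = "character",
                              embedded_term = "character"),
      zero_entity_docs = zero_docs,
      stoplist = fx$manifest$stoplist
    )
  ), class = "chem_fixture_corpus")
}

#' Write a fixture corpus to disk
#'
#' Emits one `.txt` and one `.ann` file per document plus a JSON manifest of
#' the planted structure.
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc_id in names(corpus$docs)) {
    con <- file(file.path(dir, paste0(doc_id, ".txt")), "wt", encoding = "UTF-8")
    writeLines(corpus$docs[[doc_id]], con, sep = "")
    close(con)
  }
  write_gold(corpus$gold, dir, doc_ids = names(corpus$docs))
  jsonlite::write_json(corpus$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
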