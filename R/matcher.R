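KEY_SEP <- "\u0001"

# normalized token-sequence key for a term surface, with ignored and empty
# tokens dropped; "" when nothing remains
term_key <- function(surface, tok_cfg, ignored) {
  toks <- tokenize(surface, tok_cfg)
  keys <- toks$normalized[nzchar(toks$normalized) & !toks$normalized %in% ignored]
  paste(keys, collapse = KEY_SEP)
}

#' Build a term index for matching
#'
#' Every active dictionary term is tokenized and normalized; tokens on the
#' ignored list (non-informative words like "of", "the", "and", "in") are
#' deleted from the key sequence. Removed terms never enter the index. Terms
#' whose tokens all normalize away are excluded with a warning and recorded
#' in the index's `dropped` field.
#'
#' @param d a [chem_dictionary()].
#' @param tok_cfg a [tokenizer_config()]; matching must use the same
#'   configuration as indexing.
#' @param ignored non-informative tokens to skip.
#' @return an object of class `term_index`.
#' @export
build_index <- function(d, tok_cfg = tokenizer_config(),
                        ignored = c("of", "the", "and", "in")) {
  validate_dictionary(d)
  map <- new.env(hash = TRUE, parent = emptyenv())
  at <- active_terms(d)
  dropped <- character()
  max_len <- 0L
  for (i in seq_len(nrow(at))) {
    surf <- at$surface[i]
    key <- term_key(surf, tok_cfg, ignored)
    if (!nzchar(key)) {
      dropped <- c(dropped, surf)
      next
    }
    entry <- data.frame(concept_id = at$concept_id[i], surface = surf,
                        preferred = at$preferred[i], stringsAsFactors = FALSE)
    map[[key]] <- if (is.null(map[[key]])) entry else rbind(map[[key]], entry)
    max_len <- max(max_len, length(strsplit(key, KEY_SEP, fixed = TRUE)[[1]]))
  }
  if (length(dropped)) {
    warning(length(dropped), " term(s) normalized to an empty token sequence",
            " and were excluded from the index")
  }
  structure(
    list(map = map, max_len = max_len, ignored = ignored, tok_cfg = tok_cfg,
         dropped = dropped),
    class = "term_index"
  )
}

#' @export
print.term_index <- function(x, ...) {
  cat("<term_index> ", length(ls(x$map)), " keys, max length ", x$max_len,
      ", ", length(x$dropped), " dropped term(s)\n", sep = "")
  invisible(x)
}

annotation_columns <- function() {
  empty_df(doc_id = "character", start = "integer", end = "integer",
           surface = "character", matched_term = "character",
           concept_ids = "character", key = "character", status = "character")
}

#' Find concept mentions in a document
#'
#' Case-insensitive, word-order sensitive, largest-match scanning: moving
#' left to right over the document's tokens, the longest indexed token
#' sequence starting at the current position is emitted and matching resumes
#' after it, so annotations never overlap. Ignored tokens inside a window are
#' skipped for key comparison but remain covered by the reported span. Span
#' offsets are 0-based half-open over the raw text and cover the matched
#' tokens' cores (leading/trailing punctuation stripped during normalization
#' is excluded).
#'
#' @param doc document text.
#' @param idx a [build_index()] result.
#' @param doc_id identifier recorded on each annotation.
#' @return data.frame of annotations sorted by `start`: `doc_id`, `start`,
#'   `end`, `surface`, `matched_term`, `concept_ids` (";"-joined), `key`,
#'   `status` (initially `"kept"`).
#' @export
find_matches <- function(doc, idx, doc_id = "doc") {
  stopifnot(inherits(idx, "term_index"))
  toks <- tokenize(doc, idx$tok_cfg)
  out <- annotation_columns()
  if (!nrow(toks) || idx$max_len == 0L) return(out)
  ci <- which(nzchar(toks$normalized) & !toks$normalized %in% idx$ignored)
  n <- length(ci)
  if (!n) return(out)
  norm <- toks$normalized
  rows <- list()
  p <- 1L
  while (p <= n) {
    matched_len <- 0L
    for (len in seq.int(min(idx$max_len, n - p + 1L), 1L)) {
      key <- paste(norm[ci[p:(p + len - 1L)]], collapse = KEY_SEP)
      pay <- idx$map[[key]]
      if (!is.null(pay)) {
        first <- ci[p]
        last <- ci[p + len - 1L]
        start <- toks$core_start[first]
        end <- toks$core_end[last]
        pay <- pay[order(pay$surface), , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = doc_id, start = start, end = end,
          surface = substr(doc, start + 1L, end),
          matched_term = pay$surface[1],
          concept_ids = paste(sort(unique(pay$concept_id)), collapse = ";"),
          key = key, status = "kept", stringsAsFactors = FALSE
        )
        matched_len <- len
        break
      }
    }
    p <- p + max(matched_len, 1L)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Tag a corpus
#'
#' Runs [find_matches()] over a named vector of documents and binds the
#' results.
#'
#' @param docs named character vector of document texts.
#' @param idx a [build_index()] result.
#' @return annotation data.frame across all documents.
#' @export
tag_corpus <- function(docs, idx) {
  ids <- names(docs) %||% as.character(seq_along(docs))
  res <- lapply(seq_along(docs), function(k) find_matches(docs[[k]], idx, ids[k]))
  out <- do.call(rbind, c(list(annotation_columns()), res))
  rownames(out) <- NULL
  out
}

#' Write annotations as brat-style standoff or TSV
#'
#' Standoff lines have the form `T<n>\tCHEM <start> <end>\t<surface>` with a
#' companion `#<n>\tAnnotatorNotes T<n>\t<concept_ids>` note per annotation.
#'
#' @param ann annotation data.frame (one document's worth for brat output).
#' @param path output file.
#' @param format `"brat"` or `"tsv"`.
#' @param label entity label used in brat output.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, format = c("brat", "tsv"),
                              label = "CHEM") {
  format <- match.arg(format)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "brat") {
    for (i in seq_len(nrow(ann))) {
      writeLines(sprintf("T%d\t%s %d %d\t%s", i, label, ann$start[i],
                         ann$end[i], ann$surface[i]), con)
      writeLines(sprintf("#%d\tAnnotatorNotes T%d\t%s", i, i,
                         ann$concept_ids[i]), con)
    }
  } else {
    out <- ann
    out$key <- gsub(KEY_SEP, " ", out$key, fixed = TRUE)
    writeLines(paste(names(out), collapse = "\t"), con)
    if (nrow(out)) {
      writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
    }
  }
  invisible(path)
}
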