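ENTITY_CLASSES <- c("IUPAC", "PART", "SUM", "TRIV", "ABB", "FAM")

#' Read a corpus of plain-text documents
#'
#' @param doc_dir directory containing `.txt` files, one document (abstract)
#'   per file; the document id is the file name without extension.
#' @return named character vector of document texts.
#' @export
read_corpus <- function(doc_dir) {
  files <- sort(list.files(doc_dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- vapply(files, function(f) {
    paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }, "")
  names(docs) <- sub("\\.txt$", "", basename(files))
  docs
}

#' Read gold annotations in brat-style standoff
#'
#' Each `.ann` file pairs with the `.txt` document of the same name and
#' contains entity lines `T<n>\t<CLASS> <start> <end>\t<surface>` with
#' 0-based half-open character offsets. Classes must be one of IUPAC, PART,
#' SUM, TRIV, ABB, FAM. Every span is validated against the document text.
#'
#' @param doc_dir directory of `.txt` documents.
#' @param ann_dir directory of `.ann` files (defaults to `doc_dir`).
#' @return data.frame (`doc_id`, `start`, `end`, `surface`, `class`).
#' @export
read_gold <- function(doc_dir, ann_dir = doc_dir) {
  docs <- read_corpus(doc_dir)
  files <- sort(list.files(ann_dir, pattern = "\\.ann$", full.names = TRUE))
  rows <- list()
  for (f in files) {
    doc_id <- sub("\\.ann$", "", basename(f))
    if (!doc_id %in% names(docs)) stop("no .txt document for ", basename(f))
    doc <- docs[[doc_id]]
    for (line in readLines(f, encoding = "UTF-8", warn = FALSE)) {
      if (!nzchar(line) || !startsWith(line, "T")) next
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 3L) stop("malformed annotation line in ", basename(f), ": ", line)
      meta <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      cls <- meta[1]
      if (!cls %in% ENTITY_CLASSES) {
        stop("unknown entity class '", cls, "' in ", basename(f))
      }
      start <- as.integer(meta[2])
      end <- as.integer(meta[3])
      if (is.na(start) || is.na(end) || start < 0L || end > nchar(doc) || start >= end) {
        stop("span out of range in ", basename(f), ": ", fields[1])
      }
      got <- substr(doc, start + 1L, end)
      if (got != fields[3]) {
        stop("surface mismatch for ", fields[1], " in ", basename(f),
             ": annotation says '", fields[3], "', document has '", got, "'")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = doc_id, start = start, end = end, surface = fields[3],
        class = cls, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    empty_df(doc_id = "character", start = "integer", end = "integer",
             surface = "character", class = "character")
  }
  out[order(out$doc_id, out$start), , drop = FALSE]
}

#' Write gold annotations as brat-style standoff files
#'
#' @param gold gold annotation data.frame.
#' @param dir output directory (one `.ann` file per document id).
#' @param doc_ids document ids to write files for (so documents without
#'   entities still get an empty `.ann` file).
#' @return `dir`, invisibly.
#' @export
write_gold <- function(gold, dir, doc_ids = unique(gold$doc_id)) {
  for (doc_id in doc_ids) {
    sub <- gold[gold$doc_id == doc_id, , drop = FALSE]
    lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(sub)), sub$class,
                     sub$start, sub$end, sub$surface)
    con <- file(file.path(dir, paste0(doc_id, ".ann")), "wt", encoding = "UTF-8")
    writeLines(lines, con)
    close(con)
  }
  invisible(dir)
}

span_key <- function(x) paste(x$doc_id, x$start, x$end, sep = "\r")

dedupe_spans <- function(x) x[!duplicated(span_key(x)), , drop = FALSE]

#' Exact-boundary scoring
#'
#' A predicted span is a true positive when it matches a gold span's start
#' and end exactly (per document; duplicate spans collapse before scoring).
#' Predictions without an exact gold twin are false positives — including
#' predictions in documents absent from the gold set — and unmatched gold
#' spans are false negatives.
#'
#' @param predicted kept annotations (data.frame with `doc_id`, `start`,
#'   `end`).
#' @param gold gold annotations.
#' @return an object of class `confusion_counts`: list `tp`, `fp`, `fn`.
#' @export
score <- function(predicted, gold) {
  p <- dedupe_spans(predicted)
  g <- dedupe_spans(gold)
  tp <- sum(span_key(p) %in% span_key(g))
  structure(list(tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- compute_metrics(x)
  cat(sprintf("TP %d  FP %d  FN %d  |  P %.2f  R %.2f  F %.2f\n",
              x$tp, x$fp, x$fn, m$precision, m$recall, m$f_score))
  invisible(x)
}

#' Precision, recall and F-score from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN), F = 2PR/(P+R); any quantity
#' with a zero denominator is reported as 0 by convention.
#'
#' @param counts a [score()] result (or list with `tp`, `fp`, `fn`).
#' @return list with `precision`, `recall`, `f_score`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(precision = p, recall = r, f_score = f_from_pr(p, r))
}

#' Per-entity-class recall
#'
#' @param predicted kept annotations.
#' @param gold gold annotations with a `class` column.
#' @return named numeric vector over IUPAC/PART/SUM/TRIV/ABB/FAM; classes
#'   absent from the gold set are `NA` (undefined).
#' @export
per_class_recall <- function(predicted, gold) {
  p <- dedupe_spans(predicted)
  g <- dedupe_spans(gold)
  out <- stats::setNames(rep(NA_real_, length(ENTITY_CLASSES)), ENTITY_CLASSES)
  for (cls in ENTITY_CLASSES) {
    sub <- g[g$class == cls, , drop = FALSE]
    if (!nrow(sub)) next
    out[cls] <- sum(span_key(sub) %in% span_key(p)) / nrow(sub)
  }
  out
}

overlaps_any <- function(row, other) {
  any(other$doc_id == row$doc_id & other$start < row$end & other$end > row$start &
        !(other$start == row$start & other$end == row$end))
}

#' Categorize evaluation errors
#'
#' Labels each false negative with the first applicable category:
#' `partial_match` (a kept prediction overlaps the gold span without matching
#' its boundaries), `removed_by_disambiguation` (an exact-span match existed
#' before disambiguation), `removed_by_stoplist` (the gold surface matches a
#' term removed by the frequent-terms stoplist), `tokenization_error` (the
#' gold surface is an active dictionary term verbatim yet produced no exact
#' match), `not_in_dictionary` (the surface matches no term at all), else
#' `manual_review`. False positives are labelled `partial_match` when they
#' overlap a gold span, otherwise `manual_review` — the remaining FP
#' categories (annotation error, out of corpus scope, not a chemical) require
#' human judgment.
#'
#' @param gold gold annotations.
#' @param kept kept (post-disambiguation) annotations.
#' @param pre_disambiguation matcher annotations before disambiguation.
#' @param dictionary the filtered dictionary used for matching.
#' @param removal_log removal log from [apply_removal_rules()].
#' @return list with `fn` and `fp` (the error sets with a `category`
#'   column) and `table` (named category counts, FN and FP separately).
#' @export
categorize_errors <- function(gold, kept, pre_disambiguation, dictionary,
                              removal_log) {
  if (is.null(gold) || is.null(kept) || is.null(pre_disambiguation) ||
      is.null(dictionary) || is.null(removal_log)) {
    stop("all pipeline artifacts (gold, kept and pre-disambiguation ",
         "annotations, dictionary, removal log) are required")
  }
  g <- dedupe_spans(gold)
  p <- dedupe_spans(kept)
  pre <- dedupe_spans(pre_disambiguation)
  fn <- g[!span_key(g) %in% span_key(p), , drop = FALSE]
  fp <- p[!span_key(p) %in% span_key(g), , drop = FALSE]
  all_surf <- tolower(dictionary$terms$surface)
  act_surf <- tolower(active_terms(dictionary)$surface)
  stop_surf <- tolower(removal_log$surface[removal_log$rule == "stoplist"])
  fn$category <- vapply(seq_len(nrow(fn)), function(i) {
    row <- fn[i, , drop = FALSE]
    surf <- tolower(row$surface)
    if (overlaps_any(row, p)) return("partial_match")
    if (span_key(row) %in% span_key(pre)) return("removed_by_disambiguation")
    if (surf %in% stop_surf) return("removed_by_stoplist")
    if (surf %in% act_surf) return("tokenization_error")
    if (!surf %in% all_surf) return("not_in_dictionary")
    "manual_review"
  }, "")
  fp$category <- vapply(seq_len(nrow(fp)), function(i) {
    if (overlaps_any(fp[i, , drop = FALSE], g)) "partial_match" else "manual_review"
  }, "")
  list(
    fn = fn, fp = fp,
    table = list(fn = table(fn$category), fp = table(fp$category))
  )
}
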