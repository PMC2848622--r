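#' Run the full term-identification pipeline
#'
#' Reproduces the standard four-condition comparison for a dictionary on a
#' corpus:
#' \enumerate{
#'   \item \strong{unprocessed} — the raw dictionary is indexed and matched;
#'   \item \strong{filtered} — removal rules 1-2 (trivial single tokens,
#'     suppression features) and the rewrite rules (inversion, possessive,
#'     long/short split) are applied first;
#'   \item \strong{frequent_terms} — the reviewed stoplist additionally
#'     removes common-English terms;
#'   \item \strong{disambiguation} — homonym rules discard unsupported
#'     mentions of ambiguous and risky terms.
#' }
#' When gold annotations are supplied, each stage is scored with
#' exact-boundary matching.
#'
#' @param dictionary a [chem_dictionary()].
#' @param docs named character vector of documents.
#' @param gold optional gold annotations ([read_gold()] format).
#' @param stoplist reviewed stoplist for the frequent-terms stage.
#' @param filter_cfg a [filter_config()] (its stoplist is overridden by
#'   `stoplist`).
#' @param tok_cfg a [tokenizer_config()].
#' @param disamb_cfg a [disambiguation_config()].
#' @param ignored matcher ignore list.
#' @return an object of class `chem_pipeline`: list with `report` (one row
#'   per stage: counts and metrics, `NA`-free only when gold is given),
#'   `annotations` (per-stage annotation data.frames), `dictionaries`
#'   (per-stage dictionaries), and `logs` (removal/rewrite logs).
#' @export
run_pipeline <- function(dictionary, docs, gold = NULL,
                         stoplist = character(),
                         filter_cfg = filter_config(),
                         tok_cfg = tokenizer_config(),
                         disamb_cfg = disambiguation_config(),
                         ignored = c("of", "the", "and", "in")) {
  filter_cfg$stoplist <- tolower(stoplist)
  # stage 1: unprocessed
  ann1 <- tag_corpus(docs, build_index(dictionary, tok_cfg, ignored))
  # stage 2: removal rules 1-2 + rewrites
  cfg_nostop <- filter_cfg
  cfg_nostop$stoplist <- character()
  flt <- apply_removal_rules(dictionary, cfg_nostop, tok_cfg)
  rw <- apply_rewrite_rules(flt$dictionary)
  d2 <- rw$dictionary
  ann2 <- tag_corpus(docs, build_index(d2, tok_cfg, ignored))
  # stage 3: frequent-terms stoplist
  stp <- apply_removal_rules(d2, filter_cfg, tok_cfg)
  d3 <- stp$dictionary
  ann3 <- tag_corpus(docs, build_index(d3, tok_cfg, ignored))
  # stage 4: disambiguation
  kt <- build_keyword_table(d3, disamb_cfg, tok_cfg, ignored)
  ann4 <- disambiguate(ann3, docs, d3, kt, disamb_cfg, tok_cfg, ignored)
  kept4 <- ann4[ann4$status == "kept", , drop = FALSE]
  stages <- list(unprocessed = ann1, filtered = ann2,
                 frequent_terms = ann3, disambiguation = kept4)
  report <- data.frame(stage = names(stages), tp = NA_integer_,
                       fp = NA_integer_, fn = NA_integer_,
                       precision = NA_real_, recall = NA_real_,
                       f_score = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(gold)) {
    for (i in seq_along(stages)) {
      cc <- score(stages[[i]], gold)
      m <- compute_metrics(cc)
      report$tp[i] <- cc$tp
      report$fp[i] <- cc$fp
      report$fn[i] <- cc$fn
      report$precision[i] <- m$precision
      report$recall[i] <- m$recall
      report$f_score[i] <- m$f_score
    }
  }
  structure(list(
    report = report,
    annotations = c(stages, list(disambiguation_full = ann4)),
    dictionaries = list(unprocessed = dictionary, filtered = d2,
                        frequent_terms = d3),
    logs = list(removal = rbind(flt$log, stp$log), rewrite = rw$log)
  ), class = "chem_pipeline")
}

#' @export
print.chem_pipeline <- function(x, ...) {
  cat("<chem_pipeline>\n")
  rep <- x$report
  for (col in c("precision", "recall", "f_score")) {
    rep[[col]] <- round_half_up(rep[[col]], 2)
  }
  print(rep, row.names = FALSE)
  invisible(x)
}

#' Per-class recall and error categories for a pipeline run
#'
#' Convenience wrapper computing the full evaluation report for the final
#' (disambiguated) stage of a pipeline.
#'
#' @param pipe a [run_pipeline()] result.
#' @param gold gold annotations.
#' @return list with `metrics`, `per_class`, and `errors` (see
#'   [categorize_errors()]).
#' @export
evaluate_pipeline <- function(pipe, gold) {
  kept <- pipe$annotations$disambiguation
  list(
    metrics = compute_metrics(score(kept, gold)),
    per_class = per_class_recall(kept, gold),
    errors = categorize_errors(gold, kept,
                               pre_disambiguation = pipe$annotations$frequent_terms,
                               dictionary = pipe$dictionaries$frequent_terms,
                               removal_log = pipe$logs$removal)
  )
}
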