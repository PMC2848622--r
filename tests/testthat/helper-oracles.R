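# shared fixtures and independent brute-force oracles

IGNORED <- c("of", "the", "and", "in")
SEP <- "\u0001"

# quick dictionary: named list concept_id -> character vector of surfaces
# (first surface preferred)
quick_dict <- function(concepts, identifiers = NULL, formulas = NULL) {
  terms <- do.call(rbind, lapply(names(concepts), function(cid) {
    surfs <- concepts[[cid]]
    data.frame(concept_id = cid, surface = surfs,
               preferred = seq_along(surfs) == 1L, stringsAsFactors = FALSE)
  }))
  d <- chem_dictionary(terms, identifiers)
  if (!is.null(formulas)) {
    d$concepts$formula <- formulas[d$concepts$concept_id]
  }
  d
}

norm_keys <- function(surfaces, tok_cfg = tokenizer_config()) {
  vapply(surfaces, function(s) {
    toks <- tokenize(s, tok_cfg)
    k <- toks$normalized[nzchar(toks$normalized) & !toks$normalized %in% IGNORED]
    paste(k, collapse = SEP)
  }, "")
}

# brute-force matcher oracle: enumerate every token window, keep windows whose
# key is a dictionary key, then greedy leftmost-longest selection
oracle_matches <- function(doc, term_surfaces, tok_cfg = tokenizer_config()) {
  keys <- unique(norm_keys(term_surfaces, tok_cfg))
  keys <- keys[nzchar(keys)]
  toks <- tokenize(doc, tok_cfg)
  ci <- which(nzchar(toks$normalized) & !toks$normalized %in% IGNORED)
  n <- length(ci)
  hits <- list()
  for (p in seq_len(n)) {
    for (len in seq_len(n - p + 1L)) {
      key <- paste(toks$normalized[ci[p:(p + len - 1L)]], collapse = SEP)
      if (key %in% keys) hits[[length(hits) + 1L]] <- c(p, len)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else matrix(0L, 0, 2)
  res <- list()
  p <- 1L
  while (p <= n) {
    lens <- hits[hits[, 1] == p, 2]
    if (length(lens)) {
      len <- max(lens)
      res[[length(res) + 1L]] <- data.frame(
        start = toks$core_start[ci[p]],
        end = toks$core_end[ci[p + len - 1L]]
      )
      p <- p + len
    } else {
      p <- p + 1L
    }
  }
  if (length(res)) do.call(rbind, res) else data.frame(start = integer(0), end = integer(0))
}

MATCH_VOCAB <- c("alpha", "beta", "gamma", "delta", "zeta", "kappa", "omega",
                 "oxide", "acid", "chloro", "methyl", "x1", "2", "5b")

random_match_instance <- function(seed) {
  set.seed(seed)
  n_terms <- sample(3:12, 1)
  terms <- unique(vapply(seq_len(n_terms), function(i) {
    paste(sample(MATCH_VOCAB, sample(1:3, 1), replace = TRUE), collapse = " ")
  }, ""))
  doc_words <- sample(c(MATCH_VOCAB, "filler", "words", "of", "the", "plain"),
                      sample(20:60, 1), replace = TRUE)
  list(terms = terms, doc = paste(doc_words, collapse = " "))
}

# brute-force transitive closure over the shares-an-identifier relation
oracle_merge_partition <- function(d) {
  ids <- sort(d$concepts$concept_id)
  n <- length(ids)
  keyset <- lapply(ids, function(cid) {
    sub <- d$identifiers[d$identifiers$concept_id == cid, , drop = FALSE]
    paste(sub$kind, sub$value)
  })
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- i == j || length(intersect(keyset[[i]], keyset[[j]])) > 0
    }
  }
  # transitive closure by fixpoint
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- apply(adj, 1, function(r) min(which(r)))
  lapply(split(ids, comp), sort)
}

random_merge_dict <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(3:50, 1)
  ids <- sprintf("M%03d", seq_len(n))
  terms <- data.frame(concept_id = ids, surface = paste0("name", seq_len(n)),
                      preferred = TRUE, stringsAsFactors = FALSE)
  cas_pool <- sprintf("%05d-%02d-%d", 11111 + 1:6, 11, 1)
  inchi_pool <- paste0("InChI=1S/P", 1:5)
  xref_pool <- paste0("db:", 1:4)
  rows <- list()
  for (i in seq_len(n)) {
    if (stats::runif(1) < 0.5) {
      rows[[length(rows) + 1L]] <- data.frame(concept_id = ids[i], kind = "CAS",
                                              value = sample(cas_pool, 1))
    }
    if (stats::runif(1) < 0.3) {
      rows[[length(rows) + 1L]] <- data.frame(concept_id = ids[i], kind = "InChI",
                                              value = sample(inchi_pool, 1))
    }
    if (stats::runif(1) < 0.2) {
      rows[[length(rows) + 1L]] <- data.frame(concept_id = ids[i], kind = "XREF",
                                              value = sample(xref_pool, 1))
    }
  }
  idents <- if (length(rows)) unique(do.call(rbind, rows)) else NULL
  chem_dictionary(terms, idents)
}
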