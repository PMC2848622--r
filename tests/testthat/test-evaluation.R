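test_that("gold standoff files round-trip through the fixture writer", {
  fx <- generate_dictionary(fixture_spec(seed = 17, n_concepts = 12, n_docs = 8))
  co <- generate_corpus(fx)
  dir <- withr::local_tempdir()
  write_corpus(co, dir)
  docs <- read_corpus(dir)
  expect_equal(length(docs), length(co$docs))
  expect_identical(unname(docs), unname(co$docs))
  gold <- read_gold(dir)
  expect_equal(nrow(gold), nrow(co$gold))
  expect_equal(gold$surface, co$gold$surface)
  expect_equal(gold$start, co$gold$start)
})

test_that("invalid gold annotations fail loudly", {
  dir <- withr::local_tempdir()
  writeLines("aspirin was given", file.path(dir, "d1.txt"), sep = "")
  writeLines("T1\tTRIV 0 7\twrongtx", file.path(dir, "d1.ann"))
  expect_error(read_gold(dir), "surface mismatch")
  writeLines("T1\tDRUG 0 7\taspirin", file.path(dir, "d1.ann"))
  expect_error(read_gold(dir), "unknown entity class")
  writeLines("T1\tTRIV 0 99\taspirin", file.path(dir, "d1.ann"))
  expect_error(read_gold(dir), "out of range")
})

test_that("exact-boundary scoring counts span identity only", {
  g <- data.frame(doc_id = "d1", start = c(0, 10, 20, 30, 40),
                  end = c(5, 15, 25, 35, 45), surface = "x", class = "TRIV")
  p <- g[, c("doc_id", "start", "end")]
  cc <- score(p, g)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(5, 0, 0))
  # off by one character: both an FP and an FN
  p2 <- p
  p2$start[1] <- 1
  cc2 <- score(p2, g)
  expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(4, 1, 1))
  # duplicates at one span collapse before scoring
  cc3 <- score(rbind(p, p[1, ]), g)
  expect_equal(cc3$tp, 5)
  # randomized sets equal brute-force set comparison
  set.seed(7)
  for (i in 1:20) {
    gs <- unique(data.frame(doc_id = sample(c("a", "b"), 12, TRUE),
                            start = sample(0:20, 12, TRUE)))
    gs$end <- gs$start + sample(1:5, nrow(gs), TRUE)
    ps <- unique(data.frame(doc_id = sample(c("a", "b"), 12, TRUE),
                            start = sample(0:20, 12, TRUE)))
    ps$end <- ps$start + sample(1:5, nrow(ps), TRUE)
    cc <- score(ps, gs)
    gk <- paste(gs$doc_id, gs$start, gs$end)
    pk <- paste(ps$doc_id, ps$start, ps$end)
    expect_equal(cc$tp, length(intersect(pk, gk)))
    expect_equal(cc$fp, length(setdiff(pk, gk)))
    expect_equal(cc$fn, length(setdiff(gk, pk)))
    expect_equal(cc$tp + cc$fn, length(gk))
    expect_equal(cc$tp + cc$fp, length(pk))
  }
})

test_that("metric formulas respect zero-denominator conventions", {
  m <- compute_metrics(list(tp = 2, fp = 1, fn = 2))
  expect_equal(round_half_up(m$precision, 3), 0.667)
  expect_equal(round_half_up(m$recall, 3), 0.5)
  expect_equal(round_half_up(m$f_score, 3), 0.571)
  # published headline pair reproduces its F-score
  expect_equal(round_half_up(f_from_pr(0.87, 0.19), 2), 0.31)
  # harmonic-mean identity
  for (x in c(0.2, 0.5, 0.9)) expect_equal(f_from_pr(x, x), x)
  z <- compute_metrics(list(tp = 0, fp = 0, fn = 0))
  expect_equal(unlist(z), c(precision = 0, recall = 0, f_score = 0))
})

test_that("per-class recall aggregates to overall recall", {
  g <- data.frame(doc_id = "d", start = seq(0, 90, 10), end = seq(5, 95, 10),
                  surface = "x",
                  class = rep(c("TRIV", "SUM", "IUPAC"), length.out = 10))
  p <- g[c(1:4, 7), c("doc_id", "start", "end")]
  pcr <- per_class_recall(p, g)
  # brute-force per-class counting
  for (cls in unique(g$class)) {
    sub <- g[g$class == cls, ]
    hit <- sum(paste(sub$start, sub$end) %in% paste(p$start, p$end))
    expect_equal(pcr[[cls]], hit / nrow(sub))
  }
  expect_true(is.na(pcr[["ABB"]]))
  # weighted by class sizes reconstructs overall recall
  sizes <- table(g$class)
  overall <- compute_metrics(score(p, g))$recall
  expect_equal(sum(pcr[names(sizes)] * as.numeric(sizes)) / nrow(g), overall)
  # all gold matched / no predictions
  expect_equal(per_class_recall(g, g)[["TRIV"]], 1)
  none <- per_class_recall(g[0, ], g)
  expect_equal(unname(none[unique(g$class)]), rep(0, 3))
})

test_that("false negatives partition into automatable error categories", {
  d <- quick_dict(list(B1 = "beta-cyclodextrin", A1 = c("Arsenic", "As"),
                       M1 = "methanol"))
  f <- apply_removal_rules(d, filter_config(stoplist = "methanol"))
  docs <- c(d1 = "hydroxypropyl beta-cyclodextrin with methanol. As expected more text")
  gold <- data.frame(
    doc_id = "d1",
    start = c(0L, 37L, 59L),
    end = c(31L, 45L, 63L),
    surface = c("hydroxypropyl beta-cyclodextrin", "methanol", "more"),
    class = c("IUPAC", "TRIV", "TRIV"), stringsAsFactors = FALSE
  )
  idx <- build_index(f$dictionary)
  pre <- tag_corpus(docs, idx)
  post <- disambiguate(pre, docs, f$dictionary)
  kept <- post[post$status == "kept", ]
  errs <- categorize_errors(gold, kept, pre, f$dictionary, f$log)
  cat_of <- function(surf) errs$fn$category[errs$fn$surface == surf]
  expect_equal(cat_of("hydroxypropyl beta-cyclodextrin"), "partial_match")
  expect_equal(cat_of("methanol"), "removed_by_stoplist")
  expect_equal(cat_of("more"), "not_in_dictionary")
  # the partial sub-match is an FP labelled partial_match
  expect_true("partial_match" %in% errs$fp$category)
  # every FN gets exactly one label
  expect_equal(sum(unlist(lapply(errs$table$fn, sum))), nrow(errs$fn))
  # a trap removed by disambiguation is labelled as such
  docs2 <- c(d2 = "As we show results differ")
  gold2 <- data.frame(doc_id = "d2", start = 0L, end = 2L, surface = "As",
                      class = "ABB", stringsAsFactors = FALSE)
  pre2 <- tag_corpus(docs2, build_index(f$dictionary))
  post2 <- disambiguate(pre2, docs2, f$dictionary)
  errs2 <- categorize_errors(gold2, post2[post2$status == "kept", ], pre2,
                             f$dictionary, f$log)
  expect_equal(errs2$fn$category, "removed_by_disambiguation")
  # missing artifacts are an error
  expect_error(categorize_errors(gold2, NULL, pre2, f$dictionary, f$log),
               "required")
})
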