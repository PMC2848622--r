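test_that("single trivial tokens are recognized after stop-word removal", {
  expect_true(as.logical(is_single_trivial("T")))
  expect_equal(attr(is_single_trivial("T"), "detail"), "single_character")
  expect_false(as.logical(is_single_trivial("aspirin")))
  expect_true(as.logical(is_single_trivial("XIV")))
  expect_equal(attr(is_single_trivial("XIV"), "detail"), "roman_numeral")
  expect_true(as.logical(is_single_trivial("42")))
  # stop words vanish before the single-token check
  expect_true(as.logical(is_single_trivial("of the X")))
  expect_false(as.logical(is_single_trivial("vitamin C")))
  # roman numerals: strict subtractive notation only, allowlist wins
  expect_false(as.logical(is_single_trivial("IIII")))
  expect_true(as.logical(is_single_trivial("CL")))
  expect_false(as.logical(is_single_trivial("CL", filter_config(roman_allowlist = "cl"))))
  expect_true(as.logical(is_single_trivial("mcmxcix")))
})

test_that("suppression features match the anchored patterns in order", {
  expect_equal(has_suppression_feature("unspecified phosphate of chloroquine diphosphate"),
               "unspecified")
  expect_true(is.na(has_suppression_feature("chloroquine diphosphate")))
  expect_equal(has_suppression_feature("insulin, NOS"), "nos_after_comma")
  expect_true(is.na(has_suppression_feature("noscapine")))
  expect_equal(has_suppression_feature("insulin (NOS)"), "nos_bracketed")
  expect_equal(has_suppression_feature("glucose 5% solution"), "dosage")
  expect_equal(has_suppression_feature("saline 10 ml"), "dosage")
  expect_equal(has_suppression_feature("ethanol 5-10%"), "dosage")
  expect_equal(has_suppression_feature("other alkaloids"), "other_at_boundary")
  expect_equal(has_suppression_feature("alkaloids, other"), "other_at_boundary")
  expect_true(is.na(has_suppression_feature("mother liquor")))
  expect_equal(has_suppression_feature("obsolete drug X"), "obsolete")
  expect_equal(has_suppression_feature("no name compound"), "no_prefix")
  expect_true(is.na(has_suppression_feature("nitric oxide")))
})

test_that("removal rules mark terms with one logged reason each", {
  d <- quick_dict(list(
    K1 = c("chloroquine diphosphate",
           "unspecified phosphate of chloroquine diphosphate", "T"),
    K2 = c("aspirin", "Me")
  ))
  res <- apply_removal_rules(d, filter_config(stoplist = "me"))
  expect_equal(nrow(res$log), 3L)
  expect_setequal(res$log$surface,
                  c("unspecified phosphate of chloroquine diphosphate", "T", "Me"))
  expect_equal(res$log$rule[res$log$surface == "Me"], "stoplist")
  d2 <- res$dictionary
  expect_equal(sum(d2$terms$status == "removed"), 3L)
  # active count decreased by exactly the log length
  expect_equal(sum(d$terms$status == "active") - sum(d2$terms$status == "active"),
               nrow(res$log))
  # idempotence
  res2 <- apply_removal_rules(d2, filter_config(stoplist = "me"))
  expect_equal(nrow(res2$log), 0L)
  expect_equal(res2$dictionary$terms, d2$terms)
  # replaying the log reconstructs the filtered dictionary from the raw one
  replay <- d
  for (i in seq_len(nrow(res$log))) {
    j <- which(replay$terms$concept_id == res$log$concept_id[i] &
                 replay$terms$surface == res$log$surface[i])
    replay$terms$status[j] <- "removed"
    replay$terms$removal_reason[j] <- res$log$rule[i]
  }
  expect_equal(replay$terms, d2$terms)
})

test_that("rewrite rules produce the documented forms", {
  expect_equal(syntactic_inversion("acid, gamma-vinyl-gamma-aminobutyric"),
               "gamma-vinyl-gamma-aminobutyric acid")
  expect_null(syntactic_inversion("aspirin"))
  expect_equal(syntactic_inversion("chloride, sodium"), "sodium chloride")
  # parenthesised commas do not split
  expect_null(syntactic_inversion("2-(1,3-dioxo)propane"))
  expect_equal(strip_possessive("Ringer's lactate"), "Ringer lactate")
  expect_null(strip_possessive("lactate"))
  expect_equal(strip_possessive("Crohn's and Alzheimer's mixture"),
               "Crohn and Alzheimer mixture")
  expect_equal(split_long_short_form("Hydrogen chloride (HCL)"),
               c("Hydrogen chloride", "HCL"))
  expect_null(split_long_short_form("(HCL)"))
  expect_equal(split_long_short_form("gamma-aminobutyric acid (GABA)"),
               c("gamma-aminobutyric acid", "GABA"))
})

test_that("rewriting adds tagged synonyms without touching originals", {
  d <- quick_dict(list(K1 = c("acid, gamma-vinyl-gamma-aminobutyric",
                              "Ringer's lactate",
                              "Hydrogen chloride (HCL)")))
  res <- apply_rewrite_rules(d)
  expect_equal(res$n_added, 4L) # inversion + possessive + long + short
  d2 <- res$dictionary
  expect_true(all(d$terms$surface %in% d2$terms$surface))
  expect_setequal(
    d2$terms$origin[!d2$terms$surface %in% d$terms$surface],
    c("inversion", "possessive", "longform", "shortform")
  )
  # concept count unchanged, no chaining, duplicate guard
  expect_equal(nrow(d2$concepts), nrow(d$concepts))
  res2 <- apply_rewrite_rules(d2)
  expect_equal(res2$n_added, 0L)
  # no rewritable terms -> unchanged
  plain <- quick_dict(list(K1 = "aspirin"))
  expect_equal(apply_rewrite_rules(plain)$n_added, 0L)
})

test_that("filtering never raises and rewriting never lowers the active-term count", {
  for (seed in c(2, 9, 23)) {
    fx <- generate_dictionary(fixture_spec(seed = seed, n_concepts = 25))
    d <- fx$dictionary
    n0 <- sum(d$terms$status == "active")
    f <- apply_removal_rules(d, filter_config(stoplist = fx$manifest$stoplist))
    expect_lte(sum(f$dictionary$terms$status == "active"), n0)
    r <- apply_rewrite_rules(f$dictionary)
    expect_gte(sum(r$dictionary$terms$status == "active"),
               sum(f$dictionary$terms$status == "active"))
  }
})

test_that("frequent-term candidates rank matched terms by occurrence", {
  d <- quick_dict(list(P1 = "lead", P2 = "aspirin"))
  corpus <- rep(c(doc = "lead exposure increases lead levels"), 3)
  names(corpus) <- paste0("d", 1:3)
  cand <- frequent_term_candidates(d, corpus, top_n = 500)
  expect_equal(cand$term[1], "lead")
  expect_equal(cand$count[1], 6L)
  # empty corpus -> empty candidate list
  expect_equal(nrow(frequent_term_candidates(d, character())), 0L)
  # planted frequencies equal brute-force occurrence counts
  set.seed(42)
  terms <- c("alphaxine", "betaxol", "gammadone")
  d2 <- quick_dict(stats::setNames(as.list(terms), paste0("Q", 1:3)))
  planted <- c(alphaxine = 7L, betaxol = 4L, gammadone = 1L)
  words <- c(rep(names(planted), planted), rep("filler", 20))
  docs <- vapply(split(sample(words), rep(1:4, length.out = length(words))),
                 paste, "", collapse = " ")
  cand2 <- frequent_term_candidates(d2, docs)
  expect_equal(stats::setNames(cand2$count, cand2$term),
               sort(planted, decreasing = TRUE))
})
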