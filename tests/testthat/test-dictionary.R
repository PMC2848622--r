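test_that("TSV rows aggregate into concepts with identifiers attached", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "concept_id\tterm\tpreferred\tcas\tinchi\txrefs\tsource",
    "C1\taspirin\t1\t50-78-2\t\tchebi:15365\tsrc",
    "C1\tacetylsalicylic acid\t0\t50-78-2\t\t\tsrc",
    "C1\tASA\t0\t\t\t\tsrc"
  ), path)
  d <- read_dictionary(path, "tsv")
  expect_equal(nrow(d$concepts), 1L)
  expect_equal(nrow(d$terms), 3L)
  expect_true(any(d$identifiers$kind == "CAS" & d$identifiers$value == "50-78-2"))
  expect_true(any(d$identifiers$kind == "XREF" & d$identifiers$value == "chebi:15365"))
  expect_equal(sum(d$terms$preferred), 1L)
})

test_that("malformed rows and duplicate preferred terms are rejected with location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "concept_id\tterm\tpreferred\tcas\tinchi\txrefs\tsource",
    "C1\taspirin\t1\t\t\t\tsrc",
    "C1\tASA\tmaybe\t\t\t\tsrc"
  ), path)
  expect_error(read_dictionary(path, "tsv"), "line 3")
  writeLines(c(
    "concept_id\tterm\tpreferred\tcas\tinchi\txrefs\tsource",
    "C1\taspirin\t1\t\t\t\tsrc",
    "C1\tASA\t1\t\t\t\tsrc"
  ), path)
  expect_error(read_dictionary(path, "tsv"), "C1")
})

test_that("write/read round-trips are the identity on canonical dictionaries", {
  fx <- generate_dictionary(fixture_spec(seed = 11, n_concepts = 5))
  d <- canonicalize_dictionary(fx$dictionary)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(d, path)
  d2 <- read_dictionary(path, "tsv")
  expect_equal(d2$concepts, d$concepts)
  expect_equal(d2$terms, d$terms)
  expect_equal(d2$identifiers, d$identifiers)
  # removed terms persist with their reason
  f <- apply_removal_rules(quick_dict(list(K1 = c("aspirin", "T"))),
                           filter_config())
  path_f <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(f$dictionary, path_f)
  d3 <- read_dictionary(path_f, "tsv")
  expect_equal(d3$terms$status[d3$terms$surface == "T"], "removed")
  expect_equal(d3$terms$removal_reason[d3$terms$surface == "T"], "single_trivial")
  # byte-identical re-write after canonical sorting
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(d2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("an empty dictionary writes a header-only file", {
  d <- chem_dictionary(data.frame(concept_id = character(),
                                  surface = character(),
                                  preferred = logical()))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(d, path)
  expect_length(readLines(path), 1L)
})

test_that("the minimal SKOS reader maps labels and typed notations", {
  path <- system.file("extdata", "example_dictionary_skos.xml", package = "chemlex")
  d <- read_dictionary(path, "skos")
  expect_equal(sort(d$concepts$concept_id), c("EX001", "EX002"))
  t1 <- d$terms[d$terms$concept_id == "EX001", ]
  expect_equal(t1$surface[t1$preferred], "aspirin")
  expect_true("acetylsalicylic acid" %in% t1$surface)
  i1 <- d$identifiers[d$identifiers$concept_id == "EX001", ]
  expect_setequal(i1$kind, c("CAS", "InChI"))
  expect_true("50-78-2" %in% i1$value)
})

test_that("concepts sharing identifiers merge transitively", {
  # direct share
  d <- quick_dict(list(A = "one", B = "two"),
                  data.frame(concept_id = c("A", "B"), kind = "CAS",
                             value = "50-78-2"))
  m <- merge_concepts(d)
  expect_equal(nrow(m$concepts), 1L)
  expect_setequal(m$terms$surface, c("one", "two"))
  # transitive chain A-CAS-B-InChI-C
  d <- quick_dict(list(A = "one", B = "two", C = "three"),
                  data.frame(concept_id = c("A", "B", "B", "C"),
                             kind = c("CAS", "CAS", "InChI", "InChI"),
                             value = c("50-78-2", "50-78-2", "InChI=1S/q", "InChI=1S/q")))
  m <- merge_concepts(d)
  expect_equal(nrow(m$concepts), 1L)
  expect_equal(m$concepts$concept_id, "A")
  expect_setequal(m$terms$surface, c("one", "two", "three"))
  expect_equal(m$terms$surface[m$terms$preferred], "one")
  # distinct identifiers stay apart
  d <- quick_dict(list(A = "one", B = "two"),
                  data.frame(concept_id = c("A", "B"), kind = "CAS",
                             value = c("50-78-2", "64-17-5")))
  expect_equal(nrow(merge_concepts(d)$concepts), 2L)
})

test_that("merge equals brute-force transitive closure and is order-invariant", {
  for (seed in 1:25) {
    d <- random_merge_dict(seed)
    m <- merge_concepts(d)
    part <- oracle_merge_partition(d)
    expect_setequal(m$concepts$concept_id,
                    vapply(part, function(g) g[1], ""))
    # each merged concept's term set is the union over its oracle component
    for (g in part) {
      expected <- sort(d$terms$surface[d$terms$concept_id %in% g])
      got <- sort(m$terms$surface[m$terms$concept_id == g[1]])
      expect_equal(got, expected)
    }
    # term multiset preserved overall
    expect_setequal(tolower(m$terms$surface), tolower(d$terms$surface))
    # order invariance: permute concepts/identifiers, same partition
    set.seed(seed + 1000)
    perm <- sample(nrow(d$concepts))
    d_perm <- chem_dictionary(
      d$terms[sample(nrow(d$terms)), ],
      if (nrow(d$identifiers)) d$identifiers[sample(nrow(d$identifiers)), ] else NULL,
      d$concepts[perm, ]
    )
    m2 <- merge_concepts(d_perm)
    expect_equal(canonicalize_dictionary(m2)$terms,
                 canonicalize_dictionary(m)$terms)
  }
})

test_that("overlap counts concepts sharing CAS and/or InChI values", {
  mk <- function(prefix, n, idents) {
    quick_dict(stats::setNames(as.list(paste0(prefix, "name", 1:n)),
                               paste0(prefix, sprintf("%02d", 1:n))),
               idents)
  }
  # disjoint
  d1 <- mk("a", 3, data.frame(concept_id = "a01", kind = "CAS", value = "50-78-2"))
  d2 <- mk("b", 3, data.frame(concept_id = "b01", kind = "CAS", value = "64-17-5"))
  expect_equal(compute_overlap(d1, d2)$n_overlap, 0L)
  # subset: every d1 concept matched
  ids <- data.frame(concept_id = paste0("a", sprintf("%02d", 1:3)),
                    kind = "CAS", value = sprintf("%05d-11-1", 11111:11113))
  d1 <- mk("a", 3, ids)
  ids2 <- ids
  ids2$concept_id <- paste0("b", sprintf("%02d", 1:3))
  d2 <- mk("b", 3, ids2)
  expect_equal(compute_overlap(d1, d2)$n_overlap, 3L)
  # planted: 4 shared CAS + 2 shared InChI, one concept shares both -> 5
  cas <- sprintf("%05d-22-2", 20001:20004)
  inchi <- paste0("InChI=1S/ov", 1:2)
  id1 <- rbind(
    data.frame(concept_id = paste0("a", sprintf("%02d", 1:4)), kind = "CAS", value = cas),
    data.frame(concept_id = c("a04", "a05"), kind = "InChI", value = inchi)
  )
  id2 <- rbind(
    data.frame(concept_id = paste0("b", sprintf("%02d", 1:4)), kind = "CAS", value = cas),
    data.frame(concept_id = c("b04", "b05"), kind = "InChI", value = inchi)
  )
  d1 <- mk("a", 10, id1)
  d2 <- mk("b", 10, id2)
  ov <- compute_overlap(d1, d2)
  expect_equal(ov$n_overlap, 5L)
  # symmetric in matched pair count
  expect_equal(nrow(compute_overlap(d2, d1)$pairs), nrow(ov$pairs))
})

test_that("identifier formats are validated", {
  expect_error(
    quick_dict(list(A = "x"),
               data.frame(concept_id = "A", kind = "CAS", value = "not-a-cas")),
    "CAS"
  )
  expect_error(
    quick_dict(list(A = "x"),
               data.frame(concept_id = "A", kind = "InChI", value = "1S/C2H6O")),
    "InChI"
  )
  expect_error(
    quick_dict(list(A = "x"),
               data.frame(concept_id = "A", kind = "XREF", value = "noprefix")),
    "prefix"
  )
})
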