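#' Chemical dictionary container
#'
#' A dictionary is a relational bundle of three data frames:
#' \describe{
#'   \item{concepts}{one row per chemical concept: `concept_id`, `formula`
#'     (Hill-style molecular formula or `NA`), `sources` (";"-joined origin
#'     database labels).}
#'   \item{terms}{one row per name: `concept_id`, `surface`, `preferred`
#'     (logical; exactly one per concept), `origin` (one of `source`,
#'     `inversion`, `possessive`, `longform`, `shortform`), `status`
#'     (`active`/`removed`), `removal_reason` (`single_trivial`, `feature`,
#'     `stoplist`, or `NA`). Removed terms are retained for audit, never
#'     deleted.}
#'   \item{identifiers}{one row per identifier: `concept_id`, `kind`
#'     (`CAS`, `InChI`, `XREF`), `value`. CAS values must match
#'     `dd..d-dd-d` (2-7 digits, 2 digits, 1 digit); InChI values must start
#'     with `"InChI="`; XREF values carry a `db:` source prefix.}
#' }
#'
#' @param terms data.frame as described above (missing bookkeeping columns
#'   are filled with defaults).
#' @param identifiers optional identifiers data.frame.
#' @param concepts optional concepts data.frame; derived from `terms` if
#'   absent.
#' @param provenance free-text provenance note.
#' @param validate check invariants (recommended).
#' @return an object of class `chem_dictionary`.
#' @export
chem_dictionary <- function(terms, identifiers = NULL, concepts = NULL,
                            provenance = "", validate = TRUE) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  n <- nrow(terms)
  if (is.null(terms$preferred)) terms$preferred <- rep(FALSE, n)
  if (is.null(terms$origin)) terms$origin <- rep("source", n)
  if (is.null(terms$status)) terms$status <- rep("active", n)
  if (is.null(terms$removal_reason)) terms$removal_reason <- rep(NA_character_, n)
  terms$preferred <- as.logical(terms$preferred)
  if (is.null(identifiers)) {
    identifiers <- empty_df(concept_id = "character", kind = "character",
                            value = "character")
  }
  identifiers <- as.data.frame(identifiers, stringsAsFactors = FALSE)
  if (is.null(concepts)) {
    cid <- unique(terms$concept_id)
    concepts <- data.frame(concept_id = cid,
                           formula = rep(NA_character_, length(cid)),
                           sources = rep("", length(cid)),
                           stringsAsFactors = FALSE)
  }
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  if (is.null(concepts$formula)) concepts$formula <- rep(NA_character_, nrow(concepts))
  if (is.null(concepts$sources)) concepts$sources <- rep("", nrow(concepts))
  d <- structure(list(concepts = concepts, terms = terms,
                      identifiers = identifiers,
                      provenance = as.character(provenance)),
                 class = "chem_dictionary")
  if (validate) validate_dictionary(d)
  d
}

CAS_PATTERN <- "^[0-9]{2,7}-[0-9]{2}-[0-9]$"

#' Validate dictionary invariants
#'
#' Checks concept-id uniqueness, the one-preferred-term-per-concept rule,
#' case-insensitive term uniqueness within a concept, identifier formats and
#' referential integrity. Called by constructors and readers; errors describe
#' the offending concept or value.
#'
#' @param d a [chem_dictionary()].
#' @return `d`, invisibly.
#' @export
validate_dictionary <- function(d) {
  stopifnot(inherits(d, "chem_dictionary"))
  ids <- d$concepts$concept_id
  if (anyDuplicated(ids)) {
    stop("duplicate concept_id: ", ids[duplicated(ids)][1])
  }
  orphan <- setdiff(d$terms$concept_id, ids)
  if (length(orphan)) stop("terms reference unknown concept_id: ", orphan[1])
  orphan <- setdiff(d$identifiers$concept_id, ids)
  if (length(orphan)) stop("identifiers reference unknown concept_id: ", orphan[1])
  npref <- tapply(d$terms$preferred, d$terms$concept_id, sum)
  bad <- names(npref)[npref != 1L]
  if (length(bad)) {
    stop("concept ", bad[1], " has ", npref[bad[1]],
         " preferred terms (exactly one required)")
  }
  key <- paste(d$terms$concept_id, tolower(d$terms$surface), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- d$terms[duplicated(key), , drop = FALSE]
    stop("duplicate term surface within concept ", dup$concept_id[1],
         ": ", dup$surface[1])
  }
  if (any(!nzchar(d$terms$surface))) stop("empty term surface")
  bad_reason <- xor(d$terms$status == "removed", !is.na(d$terms$removal_reason))
  if (any(bad_reason)) {
    stop("removal_reason must be present iff status == 'removed' (concept ",
         d$terms$concept_id[bad_reason][1], ")")
  }
  if (nrow(d$identifiers)) {
    idf <- d$identifiers
    bad <- idf$kind == "CAS" & !grepl(CAS_PATTERN, idf$value)
    if (any(bad)) stop("malformed CAS number: ", idf$value[bad][1])
    bad <- idf$kind == "InChI" & !startsWith(idf$value, "InChI=")
    if (any(bad)) stop("InChI value must start with 'InChI=': ", idf$value[bad][1])
    bad <- idf$kind == "XREF" & !grepl(":", idf$value, fixed = TRUE)
    if (any(bad)) stop("XREF value lacks a source-database prefix: ", idf$value[bad][1])
    bad <- !idf$kind %in% c("CAS", "InChI", "XREF")
    if (any(bad)) stop("unknown identifier kind: ", idf$kind[bad][1])
  }
  invisible(d)
}

#' @export
print.chem_dictionary <- function(x, ...) {
  act <- sum(x$terms$status == "active")
  cat("<chem_dictionary> ", nrow(x$concepts), " concepts, ",
      nrow(x$terms), " terms (", act, " active), ",
      nrow(x$identifiers), " identifiers\n", sep = "")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Active terms of a dictionary
#' @param d a [chem_dictionary()].
#' @return the `terms` rows with `status == "active"`.
#' @export
active_terms <- function(d) {
  d$terms[d$terms$status == "active", , drop = FALSE]
}

#' Canonicalize a dictionary
#'
#' Sorts concepts by `concept_id`, terms by (`concept_id`, `surface`),
#' identifiers by (`concept_id`, `kind`, `value`), and normalizes the
#' `sources` field. Reading back a written dictionary yields its canonical
#' form.
#'
#' @param d a [chem_dictionary()].
#' @return the canonicalized dictionary.
#' @export
canonicalize_dictionary <- function(d) {
  co <- d$concepts[order(d$concepts$concept_id), , drop = FALSE]
  co$sources <- vapply(co$sources, function(s) join_field(split_field(s)), "")
  tr <- d$terms[order(d$terms$concept_id, d$terms$surface), , drop = FALSE]
  idf <- unique(d$identifiers)
  idf <- idf[order(idf$concept_id, idf$kind, idf$value), , drop = FALSE]
  rownames(co) <- rownames(tr) <- rownames(idf) <- NULL
  co <- co[, c("concept_id", "formula", "sources")]
  tr <- tr[, c("concept_id", "surface", "preferred", "origin", "status", "removal_reason")]
  structure(list(concepts = co, terms = tr, identifiers = idf,
                 provenance = d$provenance),
            class = "chem_dictionary")
}

DICT_COLUMNS <- c("concept_id", "term", "preferred", "cas", "inchi", "xrefs",
                  "source", "formula", "origin", "status", "removal_reason")

#' Read a dictionary
#'
#' TSV format: one row per term with columns `concept_id`, `term`,
#' `preferred` (0/1), `cas`, `inchi`, `xrefs` (";"-separated, each value
#' `db:id`), `source`, and optionally `formula`, `origin`, `status`,
#' `removal_reason`. Rows sharing a `concept_id` aggregate into one concept;
#' identifier columns are unioned across rows. The SKOS reader understands a
#' minimal RDF/XML dialect: `skos:Concept` with `skos:prefLabel` (preferred
#' term), `skos:altLabel` (synonyms) and typed `skos:notation` elements
#' (datatype naming CAS or InChI); everything else is ignored.
#'
#' @param path file path.
#' @param format `"tsv"` or `"skos"`.
#' @return a validated [chem_dictionary()].
#' @export
read_dictionary <- function(path, format = c("tsv", "skos")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         tsv = read_dictionary_tsv(path),
         skos = read_dictionary_skos(path))
}

read_dictionary_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty dictionary file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  required <- c("concept_id", "term", "preferred", "cas", "inchi", "xrefs", "source")
  miss <- setdiff(required, header)
  if (length(miss)) stop("missing dictionary columns: ", paste(miss, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  ncol_hdr <- length(header)
  rows <- strsplit(body, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; pad
  rows <- lapply(rows, function(r) c(r, rep("", max(0L, ncol_hdr - length(r)))))
  nf <- vapply(rows, length, 0L)
  if (any(nf != ncol_hdr)) {
    i <- which(nf != ncol_hdr)[1]
    stop("malformed row at line ", i + 1L, ": expected ", ncol_hdr,
         " fields, found ", nf[i])
  }
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- header
  if (!all(tab$preferred %in% c("0", "1"))) {
    i <- which(!tab$preferred %in% c("0", "1"))[1]
    stop("malformed row at line ", i + 1L, ": preferred must be 0 or 1")
  }
  terms <- data.frame(
    concept_id = tab$concept_id,
    surface = tab$term,
    preferred = tab$preferred == "1",
    origin = if (!is.null(tab$origin)) ifelse(nzchar(tab$origin), tab$origin, "source") else "source",
    status = if (!is.null(tab$status)) ifelse(nzchar(tab$status), tab$status, "active") else "active",
    removal_reason = if (!is.null(tab$removal_reason)) {
      ifelse(nzchar(tab$removal_reason), tab$removal_reason, NA_character_)
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  npref <- tapply(terms$preferred, terms$concept_id, sum)
  bad <- names(npref)[npref > 1L]
  if (length(bad)) stop("concept ", bad[1], " has more than one preferred term")
  ids <- unique(tab$concept_id)
  id_rows <- list()
  concepts <- data.frame(concept_id = ids, formula = NA_character_,
                         sources = "", stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    sub <- tab[tab$concept_id == ids[j], , drop = FALSE]
    cas <- unique(unlist(lapply(sub$cas, split_field)))
    inchi <- unique(unlist(lapply(sub$inchi, split_field)))
    xref <- unique(unlist(lapply(sub$xrefs, split_field)))
    if (length(cas) || length(inchi) || length(xref)) {
      id_rows[[j]] <- data.frame(
        concept_id = ids[j],
        kind = c(rep("CAS", length(cas)), rep("InChI", length(inchi)),
                 rep("XREF", length(xref))),
        value = c(cas, inchi, xref),
        stringsAsFactors = FALSE
      )
    }
    f <- sub$formula
    if (!is.null(f)) {
      f <- f[nzchar(f)]
      if (length(f)) concepts$formula[j] <- f[1]
    }
    concepts$sources[j] <- join_field(unlist(lapply(sub$source, split_field)))
  }
  identifiers <- if (length(id_rows)) do.call(rbind, id_rows) else NULL
  canonicalize_dictionary(
    chem_dictionary(terms, identifiers, concepts, provenance = path)
  )
}

read_dictionary_skos <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name() = 'Concept']")
  if (!length(nodes)) stop("no skos:Concept elements found in ", path)
  terms <- list()
  id_rows <- list()
  for (i in seq_along(nodes)) {
    node <- nodes[[i]]
    about <- xml2::xml_attr(node, "about")
    cid <- if (!is.na(about)) sub(".*[/#]", "", about) else paste0("skos", i)
    pref <- xml2::xml_text(xml2::xml_find_all(node, "./*[local-name() = 'prefLabel']"))
    alt <- xml2::xml_text(xml2::xml_find_all(node, "./*[local-name() = 'altLabel']"))
    if (!length(pref)) stop("skos:Concept ", cid, " lacks a prefLabel")
    surfaces <- unique(c(pref[1], alt))
    terms[[i]] <- data.frame(concept_id = cid, surface = surfaces,
                             preferred = surfaces == pref[1],
                             origin = "source", status = "active",
                             removal_reason = NA_character_,
                             stringsAsFactors = FALSE)
    notes <- xml2::xml_find_all(node, "./*[local-name() = 'notation']")
    if (length(notes)) {
      vals <- xml2::xml_text(notes)
      dtyp <- xml2::xml_attr(notes, "datatype")
      kind <- ifelse(grepl("cas", dtyp, ignore.case = TRUE), "CAS",
              ifelse(grepl("inchi", dtyp, ignore.case = TRUE), "InChI",
              ifelse(grepl(CAS_PATTERN, vals), "CAS",
              ifelse(startsWith(vals, "InChI="), "InChI", "XREF"))))
      vals <- ifelse(kind == "XREF" & !grepl(":", vals, fixed = TRUE),
                     paste0("xref:", vals), vals)
      id_rows[[i]] <- data.frame(concept_id = cid, kind = kind, value = vals,
                                 stringsAsFactors = FALSE)
    }
  }
  canonicalize_dictionary(chem_dictionary(
    do.call(rbind, terms),
    if (length(id_rows)) do.call(rbind, id_rows) else NULL,
    provenance = path
  ))
}

#' Write a dictionary as canonical TSV
#'
#' One row per term; concepts sorted by id, terms by surface. Removal status
#' and reasons are persisted so a filtered dictionary round-trips.
#'
#' @param d a [chem_dictionary()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(d, path) {
  validate_dictionary(d)
  d <- canonicalize_dictionary(d)
  rows <- d$terms
  id_by <- split(d$identifiers, d$identifiers$concept_id)
  pick <- function(cid, kind) {
    idf <- id_by[[cid]]
    if (is.null(idf)) return("")
    join_field(idf$value[idf$kind == kind])
  }
  form <- d$concepts$formula[match(rows$concept_id, d$concepts$concept_id)]
  out <- data.frame(
    concept_id = rows$concept_id,
    term = rows$surface,
    preferred = as.integer(rows$preferred),
    cas = vapply(rows$concept_id, pick, "", kind = "CAS"),
    inchi = vapply(rows$concept_id, pick, "", kind = "InChI"),
    xrefs = vapply(rows$concept_id, pick, "", kind = "XREF"),
    source = d$concepts$sources[match(rows$concept_id, d$concepts$concept_id)],
    formula = ifelse(is.na(form), "", form),
    origin = rows$origin,
    status = rows$status,
    removal_reason = ifelse(is.na(rows$removal_reason), "", rows$removal_reason),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(DICT_COLUMNS, collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Merge concepts sharing an identifier
#'
#' Concepts are merged when they share a CAS number, a database
#' cross-reference (identical prefixed value, i.e. same source database) or
#' an InChI string; merging is transitive, so chains of shared identifiers
#' collapse into one concept. The merged concept takes the lexicographically
#' smallest member `concept_id`, the union of terms (case-insensitive
#' duplicates collapse) and identifiers, and the preferred term of the
#' smallest member id.
#'
#' @param d a [chem_dictionary()].
#' @return the merged [chem_dictionary()].
#' @export
merge_concepts <- function(d) {
  validate_dictionary(d)
  ids <- sort(d$concepts$concept_id)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (nrow(d$identifiers)) {
    key <- paste(d$identifiers$kind, d$identifiers$value, sep = "\r")
    grp <- split(match(d$identifiers$concept_id, ids), key)
    for (g in grp) {
      g <- unique(g)
      if (length(g) > 1L) for (k in 2:length(g)) union_(g[1], g[k])
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  members <- split(ids[order(comp, ids)], sort(comp))
  terms_by <- split(d$terms, d$terms$concept_id)
  ids_by <- split(d$identifiers, d$identifiers$concept_id)
  new_terms <- list()
  new_ids <- list()
  new_concepts <- list()
  for (mem in members) {
    mem <- sort(mem)
    rep_id <- mem[1]
    tr <- do.call(rbind, lapply(mem, function(m) terms_by[[m]]))
    pref_surface <- tr$surface[tr$concept_id == rep_id & tr$preferred][1]
    keep <- !duplicated(tolower(tr$surface))
    tr <- tr[keep, , drop = FALSE]
    tr$preferred <- seq_len(nrow(tr)) == match(pref_surface, tr$surface)
    tr$concept_id <- rep_id
    idf <- do.call(rbind, lapply(mem, function(m) ids_by[[m]]))
    if (!is.null(idf) && nrow(idf)) {
      idf$concept_id <- rep_id
      idf <- unique(idf)
    }
    crow <- d$concepts[match(mem, d$concepts$concept_id), , drop = FALSE]
    form <- crow$formula[!is.na(crow$formula)]
    new_concepts[[rep_id]] <- data.frame(
      concept_id = rep_id,
      formula = if (length(form)) form[1] else NA_character_,
      sources = join_field(unlist(lapply(crow$sources, split_field))),
      stringsAsFactors = FALSE
    )
    new_terms[[rep_id]] <- tr
    new_ids[[rep_id]] <- idf
  }
  canonicalize_dictionary(chem_dictionary(
    do.call(rbind, new_terms),
    do.call(rbind, new_ids[!vapply(new_ids, is.null, TRUE)]),
    do.call(rbind, new_concepts),
    provenance = d$provenance
  ))
}

#' Cross-dictionary concept overlap
#'
#' Two concepts overlap when they share a CAS number or an InChI string
#' (cross-references deliberately do not count here). The headline count is
#' the number of `d1` concepts with at least one match in `d2`.
#'
#' @param d1,d2 dictionaries.
#' @return an object of class `chem_overlap`: list with `n_overlap` and a
#'   `pairs` data.frame (`concept_id_1`, `concept_id_2`, `kind`, `value`).
#' @export
compute_overlap <- function(d1, d2) {
  validate_dictionary(d1)
  validate_dictionary(d2)
  i1 <- d1$identifiers[d1$identifiers$kind %in% c("CAS", "InChI"), , drop = FALSE]
  i2 <- d2$identifiers[d2$identifiers$kind %in% c("CAS", "InChI"), , drop = FALSE]
  pairs <- empty_df(concept_id_1 = "character", concept_id_2 = "character",
                    kind = "character", value = "character")
  if (nrow(i1) && nrow(i2)) {
    m <- merge(i1, i2, by = c("kind", "value"))
    if (nrow(m)) {
      pairs <- data.frame(concept_id_1 = m$concept_id.x,
                          concept_id_2 = m$concept_id.y,
                          kind = m$kind, value = m$value,
                          stringsAsFactors = FALSE)
      pairs <- unique(pairs)
      pairs <- pairs[order(pairs$concept_id_1, pairs$concept_id_2, pairs$kind), ]
      rownames(pairs) <- NULL
    }
  }
  structure(list(n_overlap = length(unique(pairs$concept_id_1)), pairs = pairs),
            class = "chem_overlap")
}

#' @export
print.chem_overlap <- function(x, ...) {
  cat("<chem_overlap> ", x$n_overlap, " concepts with >= 1 match (",
      nrow(x$pairs), " matched pairs)\n", sep = "")
  invisible(x)
}
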