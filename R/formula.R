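ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

#' Parse a Hill-style molecular formula
#'
#' Accepts element symbols with optional counts (e.g. `"C6H6"`, `"NaCl"`) and
#' an optional hydrate suffix introduced by a middle dot or a period (e.g.
#' `"CuSO4·5H2O"`, `"CaCl2.2H2O"`). Anything else — parenthesised groups,
#' charges, isotopes — is rejected with an error naming the offending token;
#' the downstream consistency checks only need element presence.
#'
#' @param text molecular-formula text.
#' @return list with `element_counts` (named integer vector, element symbol
#'   to count) and `hydrate_units` (non-negative integer; a bare `"H2O"`
#'   suffix counts as 1).
#' @export
parse_formula <- function(text) {
  stopifnot(length(text) == 1L)
  s <- trimws(text)
  if (!nzchar(s)) stop("empty molecular formula")
  hydrate <- 0L
  m <- regexec("^(.*?)\\s*[\u00b7.]\\s*([0-9]*)\\s*H2O$", s)[[1]]
  if (m[1] != -1L) {
    parts <- regmatches(s, list(m))[[1]]
    s <- parts[2]
    hydrate <- if (nzchar(parts[3])) as.integer(parts[3]) else 1L
    if (!nzchar(s)) stop("formula consists only of a hydrate suffix: ", text)
  }
  toks <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  if (toks[1] == -1L || sum(attr(toks, "match.length")) != nchar(s)) {
    stop("unparseable molecular formula: ", text)
  }
  pieces <- regmatches(s, list(toks))[[1]]
  sym <- sub("[0-9]*$", "", pieces)
  cnt <- sub("^[A-Z][a-z]?", "", pieces)
  bad <- !sym %in% ELEMENT_SYMBOLS
  if (any(bad)) stop("unknown element symbol '", sym[bad][1], "' in formula: ", text)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  if (any(cnt < 1L)) {
    stop("element count must be >= 1 in formula: ", text,
         " (", sym[cnt < 1L][1], ")")
  }
  counts <- tapply(cnt, sym, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(element_counts = counts, hydrate_units = hydrate)
}

# trigger word -> requirement; checked in listed order, first as whole words
FORMULA_TRIGGERS <- list(
  chloride = "Cl", bromide = "Br", iodide = "I", fluoride = "F",
  nitrite = "N", nitrate = "N",
  sulfate = "S", sulphate = "S", sulfite = "S", sulphite = "S",
  dihydrate = "hydrate2", hydrate = "hydrate1"
)

#' Name-to-formula consistency check
#'
#' The automated curation pass used before manual curation: for every active
#' term whose surface contains a trigger word, verify the concept's molecular
#' formula supports it — halide names (`chloride`, `bromide`, `iodide`,
#' `fluoride`) require the corresponding halogen; `nitrite`/`nitrate` require
#' nitrogen; `sulfate`/`sulphate`/`sulfite`/`sulphite` require sulphur;
#' `hydrate`/`dihydrate` require at least one / two waters of hydration.
#' Concepts without a formula are skipped, not flagged.
#'
#' @param d a [chem_dictionary()].
#' @return data.frame of flags (`concept_id`, `term`, `trigger`, `missing`),
#'   with attribute `skipped` listing concept ids lacking a formula.
#' @export
name_formula_consistency <- function(d) {
  validate_dictionary(d)
  flags <- list()
  skipped <- character()
  at <- active_terms(d)
  for (j in seq_len(nrow(d$concepts))) {
    cid <- d$concepts$concept_id[j]
    surfs <- at$surface[at$concept_id == cid]
    if (!length(surfs)) next
    hits_any <- vapply(names(FORMULA_TRIGGERS), function(w) {
      any(grepl(paste0("\\b", w, "\\b"), surfs, ignore.case = TRUE))
    }, TRUE)
    if (!any(hits_any)) next
    form <- d$concepts$formula[j]
    if (is.na(form) || !nzchar(form)) {
      skipped <- c(skipped, cid)
      next
    }
    comp <- parse_formula(form)
    for (w in names(FORMULA_TRIGGERS)) {
      req <- FORMULA_TRIGGERS[[w]]
      hit <- grepl(paste0("\\b", w, "\\b"), surfs, ignore.case = TRUE)
      for (s in surfs[hit]) {
        ok <- if (req == "hydrate1") comp$hydrate_units >= 1L
        else if (req == "hydrate2") comp$hydrate_units >= 2L
        else req %in% names(comp$element_counts)
        if (!ok) {
          miss <- if (req == "hydrate1") "hydration water"
          else if (req == "hydrate2") "2 hydration waters" else req
          flags[[length(flags) + 1L]] <- data.frame(
            concept_id = cid, term = s, trigger = w, missing = miss,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(flags)) do.call(rbind, flags) else {
    empty_df(concept_id = "character", term = "character",
             trigger = "character", missing = "character")
  }
  attr(out, "skipped") <- unique(skipped)
  out
}
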