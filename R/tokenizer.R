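#' Tokenizer configuration
#'
#' The tokenizer treats everything that is not a letter or a digit as a word
#' delimiter, except for a configurable set of characters that commonly occur
#' inside chemical names: full stops, commas, plus signs, hyphens, single
#' quotation marks and all types of parentheses. These stay inside tokens, and
#' a post-hoc stripping pass removes them where they are clearly punctuation
#' (trailing full stops/commas, unmatched brackets, brackets that surround the
#' whole token).
#'
#' @param delimiter_exceptions characters excluded from the delimiter list
#'   (single characters).
#' @param suffix_list character vector of suffixes removed once from the end
#'   of a token during normalization (e.g. a plural "s"). Empty by default;
#'   see `system.file("extdata", "example_suffixes.txt", package = "chemlex")`
#'   for a worked example file.
#' @param strip_rules_enabled logical; disable to keep raw token surfaces.
#' @return an object of class `tokenizer_config`.
#' @export
tokenizer_config <- function(delimiter_exceptions = c(".", ",", "+", "-", "'",
                                                      "(", ")", "[", "]", "{", "}"),
                             suffix_list = character(),
                             strip_rules_enabled = TRUE) {
  stopifnot(all(nchar(delimiter_exceptions) == 1L))
  structure(
    list(delimiter_exceptions = delimiter_exceptions,
         suffix_list = as.character(suffix_list),
         strip_rules_enabled = isTRUE(strip_rules_enabled)),
    class = "tokenizer_config"
  )
}

BRACKET_OPEN <- c("(", "[", "{")
BRACKET_CLOSE <- c(")", "]", "}")

# remove bracket characters that have no partner within the token
strip_unmatched_brackets <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 0L) return(s)
  keep <- rep(TRUE, n)
  stack_pos <- integer(0)
  stack_ch <- character(0)
  for (i in seq_len(n)) {
    c_i <- ch[i]
    if (c_i %in% BRACKET_OPEN) {
      stack_pos <- c(stack_pos, i)
      stack_ch <- c(stack_ch, c_i)
      keep[i] <- FALSE # provisional: unmatched until closed
    } else if (c_i %in% BRACKET_CLOSE) {
      want <- BRACKET_OPEN[match(c_i, BRACKET_CLOSE)]
      if (length(stack_ch) && stack_ch[length(stack_ch)] == want) {
        keep[stack_pos[length(stack_pos)]] <- TRUE
        stack_pos <- stack_pos[-length(stack_pos)]
        stack_ch <- stack_ch[-length(stack_ch)]
      } else {
        keep[i] <- FALSE
      }
    }
  }
  paste(ch[keep], collapse = "")
}

# strip brackets that enclose the entire token (first char paired with last)
strip_surrounding_brackets <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(s)
  first <- substr(s, 1L, 1L)
  last <- substr(s, n, n)
  k <- match(first, BRACKET_OPEN)
  if (is.na(k) || last != BRACKET_CLOSE[k]) return(s)
  # confirm the first bracket's partner is the last character
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_len(n)) {
    if (ch[i] == first) depth <- depth + 1L
    if (ch[i] == BRACKET_CLOSE[k]) depth <- depth - 1L
    if (depth == 0L && i < n) return(s)
  }
  if (depth != 0L) return(s)
  substr(s, 2L, n - 1L)
}

# punctuation/bracket stripping applied until fixpoint; returns the surviving
# "core" substring (case preserved, suffixes untouched)
strip_token_core <- function(s) {
  repeat {
    old <- s
    s <- sub("[.,]+$", "", s)
    s <- strip_unmatched_brackets(s)
    s <- strip_surrounding_brackets(s)
    if (identical(s, old)) return(s)
  }
}

#' Normalize a token surface
#'
#' Applies, in order: (1) stripping of trailing full stops and commas,
#' (2) removal of brackets with no partner inside the token, (3) removal of
#' brackets surrounding the whole token — steps 1-3 repeated until a fixpoint
#' — then (4) removal of one matching suffix from the configured suffix list
#' and (5) lower-casing.
#'
#' @param surface raw token text.
#' @param cfg a [tokenizer_config()].
#' @return list with `normalized` (the match key) and `core` (the surface
#'   substring that survives steps 1-3; spans reported by the matcher cover
#'   the core, not removed punctuation).
#' @export
normalize_token <- function(surface, cfg = tokenizer_config()) {
  core <- if (cfg$strip_rules_enabled) strip_token_core(surface) else surface
  norm <- core
  for (suf in cfg$suffix_list) {
    ns <- nchar(suf)
    if (nchar(norm) > ns &&
        tolower(substr(norm, nchar(norm) - ns + 1L, nchar(norm))) == tolower(suf)) {
      norm <- substr(norm, 1L, nchar(norm) - ns)
      break
    }
  }
  list(normalized = tolower(norm), core = core)
}

#' Tokenize text
#'
#' Maximal runs of letters, digits and delimiter-exception characters form
#' tokens. Offsets are 0-based, half-open, and always index the raw text;
#' normalization never moves them. Each token additionally records the
#' character range of its "core" — the part left after punctuation/bracket
#' stripping — which is what annotation spans refer to.
#'
#' @param text a single document string (may be empty).
#' @param cfg a [tokenizer_config()].
#' @return data.frame with columns `surface`, `start`, `end`, `core_start`,
#'   `core_end`, `normalized`.
#' @export
tokenize <- function(text, cfg = tokenizer_config()) {
  stopifnot(length(text) == 1L)
  out_empty <- empty_df(surface = "character", start = "integer", end = "integer",
                        core_start = "integer", core_end = "integer",
                        normalized = "character")
  if (is.na(text) || !nzchar(text)) return(out_empty)
  esc <- paste0("\\", cfg$delimiter_exceptions, collapse = "")
  pat <- paste0("[\\p{L}\\p{N}", esc, "]+")
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out_empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surfaces <- substring(text, starts, starts + lens - 1L)
  norm <- lapply(surfaces, normalize_token, cfg = cfg)
  cores <- vapply(norm, `[[`, "", "core")
  offs <- integer(length(surfaces))
  for (i in seq_along(surfaces)) {
    if (nzchar(cores[i])) {
      loc <- regexpr(cores[i], surfaces[i], fixed = TRUE)
      offs[i] <- if (loc > 0L) as.integer(loc) - 1L else 0L
      if (loc < 0L) cores[i] <- surfaces[i] # interior removal: keep full span
    }
  }
  data.frame(
    surface = surfaces,
    start = starts - 1L,
    end = starts - 1L + lens,
    core_start = ifelse(nzchar(cores), starts - 1L + offs, starts - 1L),
    core_end = ifelse(nzchar(cores), starts - 1L + offs + nchar(cores), starts - 1L + lens),
    normalized = vapply(norm, `[[`, "", "normalized"),
    stringsAsFactors = FALSE
  )
}
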