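#' Round half away from zero
#'
#' Deterministic "schoolbook" rounding used for all reported metrics, so that
#' e.g. 0.125 rounds to 0.13 regardless of the platform's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' F-score from precision and recall
#'
#' Harmonic mean 2PR/(P+R); returns 0 when P + R = 0.
#'
#' @param p precision in `[0, 1]`.
#' @param r recall in `[0, 1]`.
#' @return F-score.
#' @export
f_from_pr <- function(p, r) {
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

# split a ";"-joined field into a character vector, dropping empties
split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  v <- strsplit(x, ";", fixed = TRUE)[[1]]
  v[nzchar(v)]
}

join_field <- function(v) paste(sort(unique(v)), collapse = ";")

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_df <- function(...) {
  cols <- list(...)
  structure(
    lapply(cols, function(cl) vector(cl, 0L)),
    names = names(cols),
    class = "data.frame", row.names = integer(0)
  )
}
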