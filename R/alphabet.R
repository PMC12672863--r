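#' The 27-symbol transcript alphabet
#'
#' The fixed ordered vocabulary used throughout the package: the 26 lowercase
#' letters `a`--`z` followed by the space character. The space symbol is a
#' structural token marking word boundaries; in transcribed speech it acts as
#' a proxy for pausing behaviour, which is why it is retained as a modelled
#' state rather than stripped.
#'
#' @return Character vector of length 27: `c("a", ..., "z", " ")`.
#' @examples
#' alphabet()
#' alphabet_size()
#' @export
alphabet <- function() {
  c(letters, " ")
}

#' @rdname alphabet
#' @export
alphabet_size <- function() 27L

#' Column-safe symbol names
#'
#' Symbols as used in CSV headers and feature-matrix column names: identical
#' to [alphabet()] except that the space character is serialised as the
#' literal token `"space"` to avoid whitespace-parsing ambiguity.
#'
#' @return Character vector of length 27.
#' @export
alphabet_names <- function() {
  c(letters, "space")
}

#' Map symbols to alphabet indices
#'
#' @param symbols Character vector of single symbols (members of
#'   [alphabet()]; `"space"` is accepted as an alias for `" "`).
#' @return Integer vector of 1-based indices into [alphabet()].
#' @examples
#' alphabet_index(c("a", " ", "z"))
#' @export
alphabet_index <- function(symbols) {
  symbols[symbols == "space"] <- " "
  idx <- match(symbols, alphabet())
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("symbols outside the 27-character alphabet: ",
         paste(dQuote(bad, FALSE), collapse = ", "), call. = FALSE)
  }
  idx
}

space_index <- function() 27L
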