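# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, either case).
#' @return Character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    chartr("ACGTNacgtn", "TGCANTGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

is_dna <- function(x) grepl("^[ACGTN]+$", x)

# last/first character of a string (1-based helpers)
str_last <- function(s) substr(s, nchar(s), nchar(s))
str_first <- function(s) substr(s, 1L, 1L)
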