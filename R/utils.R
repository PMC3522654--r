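# Small sequence helpers shared across modules.  Sequences travel through the
# package as plain uppercase character strings over {A,C,G,T,N}; Biostrings
# does the heavy lifting at the file boundary.

#' Reverse complement of a DNA string
#'
#' `N` complements to `N`.
#'
#' @param x A character vector of DNA strings.
#' @return A character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uppercase and collapse every non-ACGT letter (IUPAC ambiguity codes,
# gaps, anything else) to N.  N never matches a consensus base downstream,
# so this is the conservative reading of ambiguous input.
clean_dna <- function(x) {
  gsub("[^ACGT]", "N", toupper(x))
}

# i.i.d. random DNA with a given GC content; relies on the caller having
# seeded the RNG.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Round-half-up to integer: 12.5 -> 13, 6.25 -> 6.
round_half_up <- function(x) floor(x + 0.5)

# substring as character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Safe substring on a possibly-wrapped coordinate system is not needed
# internally: all planted features live away from the origin.  Scanning
# functions handle circular topology by appending a prefix (see
# `wrap_sequence()`).
wrap_sequence <- function(seq, extra) {
  if (extra <= 0) return(seq)
  paste0(seq, substr(seq, 1L, min(extra, nchar(seq))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
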