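`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(pat, x)
}

assert_dna <- function(x, what, allow_n = FALSE) {
  if (!is_dna(x, allow_n = allow_n)) {
    stop(what, " must be an uppercase DNA string over {",
         if (allow_n) "A,C,G,T,N" else "A,C,G,T", "}", call. = FALSE)
  }
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# en dash, as conventionally printed in coordinate spans ("290-309")
EN_DASH <- "\u2013"
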