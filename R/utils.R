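# Small internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' @noRd
comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# One-letter amino acid for a codon ("*" = stop). Table lookup against the
# standard genetic code; classification and naming both go through here.
#' @noRd
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (anyNA(aa)) stop("invalid codon: ", paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

# Split a coding sequence into codon triplets.
#' @noRd
codon_split <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' @noRd
is_dna_string <- function(x) {
  nzchar(x) & !grepl("[^ACGT]", x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
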