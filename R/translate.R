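# Codon-level translation helpers. Candidate discovery needs translation that
# (a) stops at the first in-frame stop, (b) can optionally read through stops
# (for 3'UTR frame composition), and (c) renders any codon containing a
# non-ACGT base as 'X' which never terminates translation.

.codon_table <- local({
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- toupper(names(tab))
  tab
})

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a nucleotide string codon by codon
#'
#' Standard-code translation starting at `orf_start` (1-based). Translation
#' proceeds until the first in-frame stop codon unless `through_stop = TRUE`,
#' in which case stops are emitted as `*` and translation continues to the end
#' of the sequence (or `max_aa` residues). Codons containing a base outside
#' `A,C,G,T` translate to `X` and never act as stop codons. A trailing partial
#' codon is ignored and reported.
#'
#' @param seq Nucleotide string (uppercase or lowercase).
#' @param orf_start 1-based position of the first codon base.
#' @param through_stop Translate through stop codons, emitting `*`.
#' @param max_aa Maximum number of residues to emit (`Inf` = no limit).
#' @return A list with elements `aa` (amino-acid string, stop not included
#'   unless reading through), `stop_reached` (logical), and `truncated`
#'   (logical; `TRUE` when the final codon was incomplete).
#' @examples
#' translate_to_stop("ATGCCTGAATAG")$aa  # "MPE"
#' @export
translate_to_stop <- function(seq, orf_start = 1L, through_stop = FALSE,
                              max_aa = Inf) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  stopifnot(length(orf_start) == 1L, orf_start >= 1L)
  if (orf_start > n) {
    return(list(aa = "", stop_reached = FALSE, truncated = FALSE))
  }
  starts <- seq.int(orf_start, n, by = 3L)
  full <- starts + 2L <= n
  truncated <- any(!full)
  starts <- starts[full]
  if (!length(starts)) {
    return(list(aa = "", stop_reached = FALSE, truncated = truncated))
  }
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(.codon_table[codons])
  aa[is.na(aa)] <- "X"  # any codon containing N (or other) -> X, never a stop
  stop_at <- which(aa == "*")
  stop_reached <- length(stop_at) > 0L
  if (stop_reached && !through_stop) {
    aa <- aa[seq_len(stop_at[1L] - 1L)]
  }
  if (is.finite(max_aa) && length(aa) > max_aa) aa <- aa[seq_len(max_aa)]
  list(aa = paste(aa, collapse = ""),
       stop_reached = stop_reached,
       truncated = truncated)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Nucleotide string.
#' @return Reverse-complemented uppercase string.
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(as.character(seq)))))
}
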