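# Cross-species frame analysis: three-frame ORF scanning of last exons and
# hypergeometric testing of candidate overlap between species restricted to
# 1:1 orthologues.

#' Three-frame ORF scan of a last exon
#'
#' Translates the exon from its start in each of the three forward frames;
#' the ORF length of a frame is the number of residues from the frame's
#' first codon to its first stop codon (stop excluded; no ATG requirement,
#' since the frames continue an upstream coding sequence). Frames are
#' relabelled so the annotated reading frame is frame 0; the other two are
#' +1 and -1 by offset difference. Frames longer than `min_len` residues are
#' highlighted.
#'
#' @param exon_seq Nucleotide string of the last exon (transcript
#'   orientation).
#' @param annotated_offset Offset (0, 1 or 2) of the annotated frame within
#'   the exon.
#' @param min_len Highlight threshold in residues; strictly more than
#'   `min_len` is required (default 50).
#' @return List with `lengths` (named vector over frames `-1`, `0`, `+1`),
#'   `highlighted` (character vector of frame labels) and `aa` (named list
#'   of the translated frames).
#' @export
scan_last_exon <- function(exon_seq, annotated_offset = 0L, min_len = 50L) {
  exon_seq <- toupper(as.character(exon_seq))
  stopifnot(nchar(exon_seq) >= 3L, annotated_offset %in% 0:2)
  res <- lapply(0:2, function(off) {
    translate_to_stop(exon_seq, orf_start = 1L + off)
  })
  lens <- vapply(res, function(r) nchar(r$aa), integer(1))
  aa <- lapply(res, `[[`, "aa")
  # offset difference 0 -> frame 0, +1 -> frame +1, +2 -> frame -1
  rel <- (0:2 - annotated_offset) %% 3L
  label <- c("0", "+1", "-1")[rel + 1L]
  names(lens) <- label
  names(aa) <- label
  ord <- match(c("-1", "0", "+1"), label)
  lens <- lens[ord]; aa <- aa[ord]
  list(lengths = lens, highlighted = names(lens)[lens > min_len], aa = aa)
}

#' Upper-tail hypergeometric test of candidate-set overlap
#'
#' Probability of observing an overlap of at least `k` between a set of `K`
#' and a set of `n` candidates drawn from a universe of `N` genes:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param N Universe size (e.g. 1:1-orthologous candidate loci).
#' @param K,n Sizes of the two candidate sets within the universe.
#' @param k Observed overlap.
#' @return List with `N`, `K`, `n`, `k` and `p_value`.
#' @export
ortholog_overlap_test <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    stop("infeasible counts: need k <= min(K, n) <= N")
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(N = N, K = K, n = n, k = k, p_value = p)
}

#' Overlap test from orthologue map and candidate id sets
#'
#' Restricts both candidate sets to genes with a 1:1 orthologue relationship
#' and tests their overlap. The universe defaults to all 1:1 pairs for which
#' either species has a candidate; it can be overridden.
#'
#' @param ortho data.frame with columns `species_a`, `species_b` (1:1 gene id
#'   pairs; ids appearing more than once on either side are dropped).
#' @param set_a,set_b Candidate gene ids of the two species (on the id
#'   spaces of `species_a` / `species_b`).
#' @param universe Optional universe size; default described above.
#' @return As [ortholog_overlap_test()], plus the retained set sizes.
#' @export
overlap_from_sets <- function(ortho, set_a, set_b, universe = NULL) {
  stopifnot(all(c("species_a", "species_b") %in% names(ortho)))
  one2one <- !(ortho$species_a %in% ortho$species_a[duplicated(ortho$species_a)]) &
             !(ortho$species_b %in% ortho$species_b[duplicated(ortho$species_b)])
  om <- ortho[one2one, , drop = FALSE]
  a_in <- om$species_a %in% set_a
  b_in <- om$species_b %in% set_b
  K <- sum(a_in); n <- sum(b_in); k <- sum(a_in & b_in)
  N <- if (is.null(universe)) sum(a_in | b_in) else universe
  ortholog_overlap_test(N, K, n, k)
}
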