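# Amino-acid composition, SH3-binding proline-rich motif scoring,
# proline-delta stability grouping and coil-fraction disorder summaries for
# canonical (fl) versus frameshift (fs) C-termini.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# UniProt/SwissProt release-average amino-acid composition (percent),
# normalised to sum to 1. Used as the default motif background when no
# proteome FASTA is supplied.
.SWISSPROT_FREQ <- local({
  p <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.72, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
         M = 2.41, F = 3.86, P = 4.74, S = 6.65, T = 5.36, W = 1.10,
         Y = 2.92, V = 6.86)
  p / sum(p)
})

#' Default hydrophobic residue class for class I/II SH3 motifs
#'
#' The hydrophobic position of class I (`[RK]x.Px.P` with hydrophobic
#' positions) and class II SH3-ligand motifs is not fixed by convention;
#' this default follows common SH3-ligand usage and can be overridden in
#' [builtin_motifs()].
#' @export
PHI_DEFAULT <- c("A", "V", "I", "L", "M", "F", "W", "Y", "P")

#' Amino-acid composition of a sequence
#'
#' Fractions over the 20 standard amino acids; `*` (stop) and `X` (unknown)
#' are excluded from numerator and denominator.
#'
#' @param seq Amino-acid string.
#' @return Named numeric vector of length 20 summing to 1, with attributes
#'   `"length"` (countable residues) and `"raw_length"`.
#' @export
aa_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  chars <- strsplit(toupper(seq), "")[[1]]
  countable <- chars[chars %in% .AA20]
  if (!length(countable)) {
    stop("sequence has no countable residues (only stop/X symbols)")
  }
  counts <- table(factor(countable, levels = .AA20))
  frac <- as.numeric(counts) / length(countable)
  names(frac) <- .AA20
  attr(frac, "length") <- length(countable)
  attr(frac, "raw_length") <- length(chars)
  frac
}

#' Proline content of a sequence, in percent
#' @param seq Amino-acid string.
#' @return Percent of countable residues that are proline.
#' @export
proline_content <- function(seq) 100 * aa_composition(seq)[["P"]]

#' 3'UTR amino-acid composition in three frames, and last-100-AA CDS profile
#'
#' Translates up to `n_aa` residues in each of the three frames starting at
#' the first base after the annotated stop codon, reading THROUGH internal
#' stop codons (stops excluded from the composition), and averages the
#' per-residue content over the three frames. The paired CDS profile is the
#' composition of the last `n_aa` residues of the annotated protein.
#'
#' @param t A `TranscriptModel`.
#' @param genome Genome from [load_genome()].
#' @param n_aa Number of residues per frame (default 100).
#' @return List with `utr` (average fractions over frames), `frames` (3 x 20
#'   matrix of per-frame fractions), `cds` (last-`n_aa` CDS composition).
#' @export
utr_composition <- function(t, genome, n_aa = 100L) {
  mrna <- spliced_sequence(t, genome)
  utr <- substring(mrna, t$orf_end + 1L)
  if (nchar(utr) < 3L) stop("3'UTR shorter than one codon for ", t$transcript_id)
  frames <- lapply(0:2, function(off) {
    translate_to_stop(utr, orf_start = 1L + off, through_stop = TRUE,
                      max_aa = n_aa)$aa
  })
  profs <- lapply(frames, function(aa) {
    if (!nchar(aa) || !any(strsplit(aa, "")[[1]] %in% .AA20)) NULL
    else aa_composition(aa)
  })
  if (all(vapply(profs, is.null, logical(1)))) {
    stop("no countable residues in any 3'UTR frame for ", t$transcript_id)
  }
  fr_mat <- do.call(rbind, lapply(profs, function(p) {
    if (is.null(p)) rep(NA_real_, 20L) else as.numeric(p)
  }))
  colnames(fr_mat) <- .AA20
  avg <- colMeans(fr_mat, na.rm = TRUE)
  protein <- translate_to_stop(mrna, t$orf_start)$aa
  cds_tail <- substring(protein, max(1L, nchar(protein) - n_aa + 1L))
  list(utr = avg, frames = fr_mat, cds = aa_composition(cds_tail))
}

#' Built-in SH3-binding proline-rich motif definitions
#'
#' Each motif is an ordered list of residue classes; `NULL` is the wildcard
#' `x`. The built-in set: `PxxP`, `PxxPxR`, `RxxPxxP`, class I
#' `[RK]x(phi)Px(phi)P` and class II `(phi)Px(phi)Px[RK]`, where `phi` is
#' the hydrophobic class (`phi` argument, default [PHI_DEFAULT]).
#'
#' @param phi Character vector of hydrophobic residues.
#' @return Named list of motif definitions (lists of residue-class vectors).
#' @export
builtin_motifs <- function(phi = PHI_DEFAULT) {
  list(
    PxxP    = list("P", NULL, NULL, "P"),
    PxxPxR  = list("P", NULL, NULL, "P", NULL, "R"),
    RxxPxxP = list("R", NULL, NULL, "P", NULL, NULL, "P"),
    classI  = list(c("R", "K"), NULL, phi, "P", NULL, phi, "P"),
    classII = list(phi, "P", NULL, phi, "P", NULL, c("R", "K"))
  )
}

#' Count motif matches in a sequence (overlapping occurrences)
#'
#' A match at offset `i` requires every non-wildcard position of the motif to
#' be satisfied; matches at all start offsets are counted, so overlapping
#' occurrences each count.
#'
#' @param seq Amino-acid string.
#' @param motif One motif definition (list of residue-class vectors, `NULL`
#'   = wildcard), e.g. an element of [builtin_motifs()].
#' @return Integer match count.
#' @export
scan_motif <- function(seq, motif) {
  chars <- strsplit(toupper(seq), "")[[1]]
  m <- length(motif)
  L <- length(chars)
  if (L < m) return(0L)
  hits <- 0L
  for (i in seq_len(L - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      cls <- motif[[j]]
      if (!is.null(cls) && !(chars[i + j - 1L] %in% cls)) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

#' Observed/expected frequency score of a motif in one sequence
#'
#' The chance probability of the motif is the product over pattern positions
#' of the summed background frequencies of the position's residue class
#' (wildcard = 1). The expected count is that probability times the number of
#' possible offsets, `max(0, L - m + 1)`. The score is `observed/expected`;
#' a sequence with no match scores 0, and a score of 1 means the motif occurs
#' exactly as often as expected by chance.
#'
#' @param seq Amino-acid string.
#' @param motif One motif definition.
#' @param background Named per-residue frequency vector summing to 1
#'   (default: SwissProt average; see [background_frequencies()]).
#' @return List with `observed`, `expected`, `score`.
#' @export
motif_frequency_score <- function(seq, motif,
                                  background = background_frequencies()) {
  if (abs(sum(background) - 1) > 1e-9) {
    stop("background frequencies must sum to 1")
  }
  p <- prod(vapply(motif, function(cls) {
    if (is.null(cls)) 1 else sum(background[cls])
  }, numeric(1)))
  L <- nchar(seq); m <- length(motif)
  expected <- p * max(0L, L - m + 1L)
  observed <- scan_motif(seq, motif)
  if (expected == 0 && observed > 0) {
    stop("inconsistent background: expected 0 matches but observed ", observed)
  }
  score <- if (observed == 0L) 0 else observed / expected
  list(observed = observed, expected = expected, score = score)
}

#' Background amino-acid frequencies
#'
#' Either the built-in SwissProt release average, or frequencies computed
#' from a supplied proteome FASTA (all sequences pooled; non-standard
#' residues ignored).
#'
#' @param proteome_fasta Optional path to a protein FASTA.
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
background_frequencies <- function(proteome_fasta = NULL) {
  if (is.null(proteome_fasta)) return(.SWISSPROT_FREQ)
  aas <- Biostrings::readAAStringSet(proteome_fasta)
  chars <- strsplit(paste(as.character(aas), collapse = ""), "")[[1]]
  chars <- chars[chars %in% .AA20]
  if (!length(chars)) stop("proteome FASTA has no standard residues")
  counts <- table(factor(chars, levels = .AA20))
  stats::setNames(as.numeric(counts) / length(chars), .AA20)
}

#' Proline-delta stability group of a candidate
#'
#' Groups a candidate by the difference in proline content (percent) between
#' the canonical (fl) and frameshift (fs) C-terminus:
#' `P-decreased` when `P_fl - P_fs > 3`, `P-rich` when `P_fl - P_fs < -3`,
#' `P-unchanged` otherwise (boundary values +/-3 fall in the middle class).
#'
#' @param P_fl,P_fs Proline content of the fl and fs C-terminus, percent.
#' @return Character vector of group labels (vectorised).
#' @export
proline_group <- function(P_fl, P_fs) {
  stopifnot(all(P_fl >= 0 & P_fl <= 100), all(P_fs >= 0 & P_fs <= 100))
  delta <- P_fl - P_fs
  ifelse(delta > 3, "P-decreased", ifelse(delta < -3, "P-rich", "P-unchanged"))
}

#' Coil (disorder) fraction of a secondary-structure string
#'
#' @param ss_string Per-residue labels over `C` (coil), `H` (helix),
#'   `E` (strand).
#' @return Fraction of residues labelled `C`.
#' @export
coil_fraction <- function(ss_string) {
  stopifnot(is.character(ss_string), length(ss_string) == 1L)
  if (!nchar(ss_string)) stop("empty secondary-structure string")
  chars <- strsplit(toupper(ss_string), "")[[1]]
  if (!all(chars %in% c("C", "H", "E"))) {
    stop("secondary-structure labels must be C, H or E")
  }
  sum(chars == "C") / length(chars)
}

#' Select the candidates with the largest proline gain for disorder analysis
#'
#' Picks the top `n` candidates by `P_fs - P_fl` (more proline generated in
#' the frameshift C-terminus), ties broken by candidate id, and emits both
#' C-termini with up to 10 upstream residues prepended when available.
#'
#' @param candidates data.frame with `id`, `fl_cterm`, `fs_cterm` and
#'   optionally `upstream` (residues N-terminal of the C-terminus; fewer
#'   than 10 are used as-is).
#' @param n Number of candidates to keep (default 200). If more than
#'   available, all are returned (reported via `message()`).
#' @param n_upstream Number of upstream residues to prepend (default 10).
#' @return data.frame with `id`, `delta_P`, `fl_seq`, `fs_seq`, ordered by
#'   decreasing proline gain.
#' @export
select_top_proline_delta <- function(candidates, n = 200L, n_upstream = 10L) {
  stopifnot(all(c("id", "fl_cterm", "fs_cterm") %in% names(candidates)))
  delta <- vapply(seq_len(nrow(candidates)), function(r) {
    proline_content(candidates$fs_cterm[r]) - proline_content(candidates$fl_cterm[r])
  }, numeric(1))
  ord <- order(-delta, candidates$id)
  if (n > nrow(candidates)) {
    message("select_top_proline_delta: only ", nrow(candidates),
            " candidate(s) available (asked for ", n, ")")
    n <- nrow(candidates)
  }
  sel <- ord[seq_len(n)]
  up <- if ("upstream" %in% names(candidates)) candidates$upstream else
    rep("", nrow(candidates))
  up <- vapply(up, function(u) {
    if (is.na(u) || !nchar(u)) "" else
      substring(u, max(1L, nchar(u) - n_upstream + 1L))
  }, character(1), USE.NAMES = FALSE)
  data.frame(
    id = candidates$id[sel], delta_P = delta[sel],
    fl_seq = paste0(up[sel], candidates$fl_cterm[sel]),
    fs_seq = paste0(up[sel], candidates$fs_cterm[sel]),
    stringsAsFactors = FALSE
  )
}

#' Score a set of sequences against a set of motifs
#'
#' Convenience wrapper applying [motif_frequency_score()] to every
#' (sequence, motif) pair.
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param motifs Named list of motif definitions (default
#'   [builtin_motifs()]).
#' @param background Background frequencies.
#' @return data.frame with `id`, `motif`, `observed`, `expected`, `score`.
#' @export
score_motifs <- function(seqs, motifs = builtin_motifs(),
                         background = background_frequencies()) {
  rows <- lapply(names(motifs), function(mn) {
    res <- lapply(seqs, motif_frequency_score, motif = motifs[[mn]],
                  background = background)
    data.frame(
      id = if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs),
      motif = mn,
      observed = vapply(res, `[[`, integer(1), "observed"),
      expected = vapply(res, `[[`, numeric(1), "expected"),
      score = vapply(res, `[[`, numeric(1), "score"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
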