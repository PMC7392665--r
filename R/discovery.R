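# Penultimate-exon skipping discovery: geometry classification, translation of
# the skipped isoform, gain filters and isoform deduplication.
#
# Geometry classes, by position of the annotated stop codon and the frame of
# the skipped exon:
#   Ultimate      stop in last exon, penultimate exon skipped, length %% 3 != 0
#   Penultimate   stop in the penultimate exon, which is skipped
#   Penulti_fp    penultimate skipped, frame preserved (length %% 3 == 0)
#   Penulti_short assigned at candidate construction: frameshifting penultimate
#                 skip whose new frame terminates upstream, giving a SHORTER
#                 C-terminus instead of a 3'UTR extension
#   Internal_fp / Internal_fs   internal exon skipped, frame preserved / shifted
# Only Ultimate and Penultimate events can extend translation into the 3'UTR.

.EXTENSION_CLASSES <- c("Ultimate", "Penultimate")

#' Classify every skippable exon of a transcript
#'
#' Emits one skip event per internal exon (the first and last exon are never
#' skipped). Transcripts with fewer than three exons yield an empty table.
#' Events of class `Ultimate` or `Penultimate` are eligible for the
#' 3'UTR-extension path; eligibility additionally requires the start codon to
#' lie entirely upstream of the skipped exon.
#'
#' @param t A `TranscriptModel`.
#' @return data.frame with one row per internal exon: ids, skipped exon index
#'   and genomic coordinates (transcript orientation), the four flanking
#'   coordinates of the deduplication tuple, the annotated stop position,
#'   `geometry_class` and `eligible`.
#' @export
classify_geometry <- function(t) {
  stopifnot(inherits(t, "TranscriptModel"))
  n <- nrow(t$exons)
  empty <- data.frame(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), exon_index_skipped = integer(),
    exon_length = integer(), geometry_class = character(),
    eligible = logical(), upstream_exon_end = integer(),
    exon_start = integer(), exon_end = integer(),
    downstream_exon_start = integer(), annotated_stop_position = integer(),
    stringsAsFactors = FALSE
  )
  if (n < 3L) return(empty)
  lens <- t$exon_lengths
  cum_before <- c(0L, cumsum(lens))[seq_len(n)]
  stop_idx <- t$stop_codon_exon_index
  rows <- lapply(2:(n - 1L), function(i) {
    len <- lens[i]
    cls <- if (i == n - 1L) {
      if (stop_idx == n) {
        if (len %% 3L != 0L) "Ultimate" else "Penulti_fp"
      } else if (stop_idx == n - 1L) "Penultimate" else "Other"
    } else {
      if (stop_idx > i) {
        if (len %% 3L != 0L) "Internal_fs" else "Internal_fp"
      } else "Other"
    }
    start_codon_upstream <- (t$orf_start + 2L) <= cum_before[i]
    # tx-orientation coordinates of the dedup 5-tuple
    tx_end <- function(j) if (t$strand == "+") t$exons$end[j] else t$exons$start[j]
    tx_start <- function(j) if (t$strand == "+") t$exons$start[j] else t$exons$end[j]
    data.frame(
      transcript_id = t$transcript_id, gene_id = t$gene_id, chrom = t$chrom,
      strand = t$strand, exon_index_skipped = i, exon_length = len,
      geometry_class = cls,
      eligible = cls %in% .EXTENSION_CLASSES && start_codon_upstream,
      upstream_exon_end = tx_end(i - 1L),
      exon_start = tx_start(i), exon_end = tx_end(i),
      downstream_exon_start = tx_start(i + 1L),
      annotated_stop_position = t$stop_first_genomic,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Build a frameshift candidate from one eligible skip event
#'
#' Translates the skipped-isoform mRNA from the annotated start codon,
#' locates the divergence point from the canonical protein at the amino-acid
#' level, and counts the gained residues and the subset encoded past the
#' annotated stop codon (first codon base strictly 3' of the stop codon's
#' last base, in genomic coordinates).
#'
#' @param e One row of [classify_geometry()] output with `geometry_class`
#'   `Ultimate` or `Penultimate`.
#' @param t The matching `TranscriptModel`.
#' @param genome Genome as returned by [load_genome()].
#' @return One-row data.frame: the event coordinates plus `divergence_point`,
#'   `new_cterm_aa`, `aa_gained`, `aa_beyond_stop`, `new_stop_in_last_exon`,
#'   `stop_reached`, `outcome` (`extended`/`short`/`non_stop`) and
#'   `contains_X`. An `Ultimate` event whose new frame terminates upstream
#'   with a shorter protein is relabelled `Penulti_short`.
#' @export
build_candidate <- function(e, t, genome) {
  e <- as.list(e)
  if (!e$geometry_class %in% .EXTENSION_CLASSES) {
    stop("build_candidate requires geometry_class Ultimate or Penultimate, got ",
         e$geometry_class)
  }
  i <- e$exon_index_skipped
  n <- nrow(t$exons)
  mrna_full <- spliced_sequence(t, genome)
  mrna_skip <- spliced_sequence(t, genome, skip_exon_index = i)
  canonical <- translate_to_stop(mrna_full, t$orf_start)
  novel <- translate_to_stop(mrna_skip, t$orf_start)

  ca <- strsplit(canonical$aa, "")[[1]]
  na_ <- strsplit(novel$aa, "")[[1]]
  L <- min(length(ca), length(na_))
  diffs <- if (L > 0L) which(ca[seq_len(L)] != na_[seq_len(L)]) else integer()
  div <- if (length(diffs)) diffs[1L] else L + 1L
  new_cterm <- if (div <= length(na_)) {
    paste(na_[div:length(na_)], collapse = "")
  } else ""
  aa_gained <- nchar(new_cterm)

  exons_skip <- t$exons[-i, , drop = FALSE]
  aa_beyond <- 0L
  if (aa_gained > 0L) {
    first_base_tx <- t$orf_start + 3L * (seq.int(div, length(na_)) - 1L)
    g <- .tx_to_genomic(exons_skip, t$strand, first_base_tx)
    aa_beyond <- if (t$strand == "+") sum(g > t$stop_last_genomic)
                 else                 sum(g < t$stop_last_genomic)
  }

  new_stop_in_last <- FALSE
  if (novel$stop_reached) {
    p_stop <- t$orf_start + 3L * length(na_)   # first base of the new stop
    kept <- seq_len(n)[-i]
    j <- .exon_index_of(exons_skip$end - exons_skip$start + 1L, p_stop)
    new_stop_in_last <- kept[j] == n
  }
  outcome <- if (!novel$stop_reached) "non_stop"
             else if (aa_beyond == 0L && length(na_) < length(ca)) "short"
             else "extended"
  cls <- e$geometry_class
  if (cls == "Ultimate" && outcome == "short") cls <- "Penulti_short"

  data.frame(
    transcript_id = e$transcript_id, gene_id = e$gene_id, chrom = e$chrom,
    strand = e$strand, exon_index_skipped = i, geometry_class = cls,
    upstream_exon_end = e$upstream_exon_end, exon_start = e$exon_start,
    exon_end = e$exon_end, downstream_exon_start = e$downstream_exon_start,
    annotated_stop_position = e$annotated_stop_position,
    divergence_point = div, new_cterm_aa = new_cterm,
    aa_gained = aa_gained, aa_beyond_stop = aa_beyond,
    new_stop_in_last_exon = new_stop_in_last,
    stop_reached = novel$stop_reached, outcome = outcome,
    contains_X = grepl("X", new_cterm, fixed = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Gain filters for frameshift candidates
#'
#' A candidate passes when it gains at least `min_gained` new residues of
#' which at least `min_beyond` are encoded past the annotated stop codon, a
#' new stop codon exists, and that stop lies in the last exon (the
#' NMD-escape geometry).
#'
#' @param cands Candidate table from [build_candidate()] (one or more rows).
#' @param min_gained Minimum number of new amino acids (default 20).
#' @param min_beyond Minimum residues encoded past the annotated stop
#'   (default 10).
#' @return Logical vector, one element per candidate row.
#' @export
apply_filters <- function(cands, min_gained = 20L, min_beyond = 10L) {
  cands$stop_reached & cands$new_stop_in_last_exon &
    cands$aa_gained >= min_gained & cands$aa_beyond_stop >= min_beyond
}

#' Collapse candidates that describe the same splicing event
#'
#' Candidates from different transcript isoforms are counted once when they
#' share (1) end of the upstream exon, (2) skipped-exon start, (3)
#' skipped-exon end, (4) start of the downstream exon and (5) the annotated
#' stop codon position (all genomic, on the same chromosome). The
#' representative is the lexicographically smallest transcript id.
#'
#' @param cands Candidate table.
#' @return Deduplicated candidate table with attributes `n_events` and
#'   `n_gene_loci`.
#' @export
deduplicate <- function(cands) {
  if (nrow(cands) == 0L) {
    attr(cands, "n_events") <- 0L
    attr(cands, "n_gene_loci") <- 0L
    return(cands)
  }
  key <- paste(cands$chrom, cands$upstream_exon_end, cands$exon_start,
               cands$exon_end, cands$downstream_exon_start,
               cands$annotated_stop_position, sep = ":")
  ord <- order(key, cands$transcript_id)
  cands <- cands[ord, , drop = FALSE]
  key <- key[ord]
  out <- cands[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_events") <- nrow(out)
  attr(out, "n_gene_loci") <- length(unique(out$gene_id))
  out
}

#' Run the full discovery stage over a set of transcript models
#'
#' Classifies every skippable exon, builds candidates for eligible
#' (`Ultimate`/`Penultimate`) events, applies the gain filters and
#' deduplicates across isoforms.
#'
#' @param genome Genome from [load_genome()].
#' @param transcripts List of `TranscriptModel` from [load_annotation()].
#' @param min_gained,min_beyond Filter thresholds, see [apply_filters()].
#' @return List with `events` (all classified skip events), `candidates`
#'   (all built candidates, passing or not), `passing` (deduplicated passing
#'   candidates) and `n_gene_loci`.
#' @export
discover_candidates <- function(genome, transcripts,
                                min_gained = 20L, min_beyond = 10L) {
  events <- do.call(rbind, lapply(transcripts, classify_geometry))
  if (is.null(events) || nrow(events) == 0L) {
    stop("no skippable exons in any transcript (need >= 3 exons)")
  }
  rownames(events) <- NULL
  elig <- events[events$eligible, , drop = FALSE]
  if (nrow(elig) == 0L) stop("no eligible Ultimate/Penultimate skip events")
  cands <- do.call(rbind, lapply(seq_len(nrow(elig)), function(r) {
    build_candidate(elig[r, , drop = FALSE], transcripts[[elig$transcript_id[r]]],
                    genome)
  }))
  rownames(cands) <- NULL
  passing <- deduplicate(cands[apply_filters(cands, min_gained, min_beyond), ,
                               drop = FALSE])
  list(events = events, candidates = cands, passing = passing,
       n_gene_loci = attr(passing, "n_gene_loci"))
}

#' Write the passing candidate table, C-terminus FASTA and skipped-exon BED
#'
#' @param passing Deduplicated passing candidates.
#' @param out_prefix Path prefix; writes `<prefix>_candidates.tsv`,
#'   `<prefix>_fs_cterm.fa` and `<prefix>_skipped_exons.bed` (0-based
#'   half-open).
#' @return Invisibly, the three file paths.
#' @export
write_discovery_outputs <- function(passing, out_prefix) {
  tsv <- paste0(out_prefix, "_candidates.tsv")
  fa <- paste0(out_prefix, "_fs_cterm.fa")
  bed <- paste0(out_prefix, "_skipped_exons.bed")
  cols <- c("gene_id", "transcript_id", "chrom", "strand",
            "exon_index_skipped", "upstream_exon_end", "exon_start",
            "exon_end", "downstream_exon_start", "annotated_stop_position",
            "geometry_class", "divergence_point", "aa_gained",
            "aa_beyond_stop", "new_cterm_aa")
  utils::write.table(passing[, cols], tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  aa <- Biostrings::AAStringSet(passing$new_cterm_aa)
  names(aa) <- paste0(passing$transcript_id, "_fs_exon",
                      passing$exon_index_skipped)
  Biostrings::writeXStringSet(aa, fa)
  bed_df <- data.frame(
    chrom = passing$chrom,
    start = pmin(passing$exon_start, passing$exon_end) - 1L,
    end = pmax(passing$exon_start, passing$exon_end),
    name = paste0(passing$transcript_id, "_exon", passing$exon_index_skipped),
    score = 0L, strand = passing$strand
  )
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(tsv, fa, bed))
}
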