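# Genome FASTA / GTF readers and the transcript model used throughout the
# pipeline. Coordinates are GTF-style 1-based inclusive at the interface and
# internally; exons of a model are stored in 5'->3' transcript orientation so
# downstream frame arithmetic never needs to re-check strand.

#' Load a genome FASTA into a named set of chromosome sequences
#'
#' All records are retained and uppercased. Duplicate chromosome identifiers
#' are rejected.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome id.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("genome FASTA contains no records: ", path)
  # FASTA headers may carry descriptions after the id; the id is word one
  ids <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(ids)) {
    stop("duplicate chromosome id(s) in genome FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  chars <- toupper(as.character(dss))
  names(chars) <- ids
  Biostrings::DNAStringSet(chars)
}

# Vectorised transcript-coordinate <-> genomic-coordinate mapping over an
# exon table (data.frame with start/end, ordered 5'->3' in tx orientation).
.tx_to_genomic <- function(exons, strand, pos) {
  lens <- exons$end - exons$start + 1L
  cum <- cumsum(lens)
  before <- c(0L, cum[-length(cum)])
  idx <- findInterval(pos - 1L, cum) + 1L
  if (any(pos < 1L) || any(pos > cum[length(cum)])) {
    stop("transcript position outside transcript")
  }
  off <- pos - before[idx]      # 1-based offset within exon, tx orientation
  if (strand == "+") exons$start[idx] + off - 1L else exons$end[idx] - off + 1L
}

.genomic_to_tx <- function(exons, strand, gpos) {
  lens <- exons$end - exons$start + 1L
  before <- c(0L, cumsum(lens)[-nrow(exons)])
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(exons))) {
    hit <- gpos >= exons$start[i] & gpos <= exons$end[i]
    if (!any(hit)) next
    off <- if (strand == "+") gpos[hit] - exons$start[i] + 1L
           else               exons$end[i] - gpos[hit] + 1L
    out[hit] <- before[i] + off
  }
  if (anyNA(out)) stop("genomic position not covered by transcript exons")
  out
}

.exon_index_of <- function(exon_lengths, pos) {
  cum <- cumsum(exon_lengths)
  findInterval(pos - 1L, cum) + 1L
}

.new_transcript_model <- function(transcript_id, gene_id, chrom, strand,
                                  biotype, exons, orf_start, orf_end,
                                  stop_codon_exon_index, stop_first_genomic,
                                  stop_last_genomic) {
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    chrom = chrom, strand = strand, biotype = biotype,
    exons = exons,                       # 5'->3' tx orientation, genomic coords
    exon_lengths = exons$end - exons$start + 1L,
    orf_start = orf_start, orf_end = orf_end,  # tx-relative, stop codon included
    stop_codon_exon_index = stop_codon_exon_index,
    stop_first_genomic = stop_first_genomic,   # stop codon first base (tx sense)
    stop_last_genomic = stop_last_genomic
  ), class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s) %s:%s %d exon(s), ORF %d-%d, stop in exon %d\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$orf_start, x$orf_end, x$stop_codon_exon_index))
  invisible(x)
}

#' Load protein-coding transcript models from a GTF annotation
#'
#' Parses an Ensembl-dialect GTF (features `exon`, `CDS`, `stop_codon`;
#' attributes `gene_id`, `transcript_id`, `transcript_biotype` or
#' `gene_biotype`) and returns validated transcript models. Only
#' protein-coding transcripts are kept. Transcripts lacking an annotated stop
#' codon, with an ORF length not divisible by three, with a non-canonical
#' stop codon, or with a non-contiguous ORF are dropped; counts of dropped
#' transcripts are attached as attribute `"dropped"` and reported via
#' `message()`.
#'
#' @param path Path to a GTF file.
#' @param genome Genome as returned by [load_genome()].
#' @return List of `TranscriptModel` objects, named by transcript id, with a
#'   `"dropped"` attribute (named integer vector of drop reasons).
#' @export
load_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  need <- c("type", "gene_id", "transcript_id")
  if (!all(need %in% colnames(mc))) {
    stop("GTF lacks required attributes: ",
         paste(setdiff(need, colnames(mc)), collapse = ", "))
  }
  biotype <- if ("transcript_biotype" %in% colnames(mc)) {
    as.character(mc$transcript_biotype)
  } else NULL
  gb <- if ("gene_biotype" %in% colnames(mc)) as.character(mc$gene_biotype) else NULL
  if (is.null(biotype)) biotype <- gb
  if (is.null(biotype)) stop("GTF lacks transcript_biotype/gene_biotype attributes")
  if (!is.null(gb)) biotype[is.na(biotype)] <- gb[is.na(biotype)]

  keep <- as.character(mc$type) %in% c("exon", "CDS", "stop_codon")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    gene_id = as.character(mc$gene_id),
    transcript_id = as.character(mc$transcript_id),
    biotype = biotype,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  df <- df[!is.na(df$transcript_id), , drop = FALSE]

  dropped <- c(not_protein_coding = 0L, no_stop_codon = 0L,
               orf_not_multiple_of_3 = 0L, noncanonical_stop = 0L,
               noncontiguous_orf = 0L, no_cds = 0L)
  models <- list()
  for (tid in unique(df$transcript_id)) {
    rows <- df[df$transcript_id == tid, , drop = FALSE]
    bt <- rows$biotype[1L]
    if (!identical(bt, "protein_coding")) {
      dropped["not_protein_coding"] <- dropped["not_protein_coding"] + 1L
      next
    }
    ex <- rows[rows$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) stop("transcript without exon features: ", tid)
    chrom <- unique(ex$chrom); strand <- unique(ex$strand)
    if (length(chrom) != 1L || length(strand) != 1L || !strand %in% c("+", "-")) {
      stop("transcript spans chromosomes or has inconsistent strand: ", tid)
    }
    if (!chrom %in% names(genome)) {
      stop("exon on chromosome absent from genome: ", chrom, " (", tid, ")")
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons within transcript: ", tid)
    }
    if (any(ex$start < 1L) || any(ex$end > length(genome[[chrom]]))) {
      stop("exon outside chromosome bounds: ", tid)
    }
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    exons <- data.frame(start = ex$start, end = ex$end)

    cds <- rows[rows$type == "CDS", , drop = FALSE]
    stp <- rows[rows$type == "stop_codon", , drop = FALSE]
    if (nrow(cds) == 0L) { dropped["no_cds"] <- dropped["no_cds"] + 1L; next }
    if (nrow(stp) == 0L) { dropped["no_stop_codon"] <- dropped["no_stop_codon"] + 1L; next }

    ends_tx <- .genomic_to_tx(exons, strand, c(cds$start, cds$end, stp$start, stp$end))
    orf_start <- min(ends_tx); orf_end <- max(ends_tx)
    orf_len <- orf_end - orf_start + 1L
    covered <- sum(cds$end - cds$start + 1L) + sum(stp$end - stp$start + 1L)
    if (covered != orf_len) {
      dropped["noncontiguous_orf"] <- dropped["noncontiguous_orf"] + 1L; next
    }
    if (orf_len %% 3L != 0L) {
      dropped["orf_not_multiple_of_3"] <- dropped["orf_not_multiple_of_3"] + 1L; next
    }
    model <- .new_transcript_model(
      tid, rows$gene_id[1L], chrom, strand, bt, exons,
      orf_start, orf_end,
      stop_codon_exon_index = .exon_index_of(exons$end - exons$start + 1L,
                                             orf_end - 2L),
      stop_first_genomic = .tx_to_genomic(exons, strand, orf_end - 2L),
      stop_last_genomic = .tx_to_genomic(exons, strand, orf_end)
    )
    stop_seq <- substr(spliced_sequence(model, genome), orf_end - 2L, orf_end)
    if (!stop_seq %in% .STOP_CODONS) {
      dropped["noncanonical_stop"] <- dropped["noncanonical_stop"] + 1L; next
    }
    models[[tid]] <- model
  }
  if (sum(dropped) > 0L) {
    message("load_annotation: dropped ",
            paste(sprintf("%s=%d", names(dropped)[dropped > 0L],
                          dropped[dropped > 0L]), collapse = ", "))
  }
  attr(models, "dropped") <- dropped
  models
}

#' Spliced (mature) transcript sequence, optionally with one exon skipped
#'
#' Concatenates exon sequences in transcript orientation (reverse-complemented
#' for minus-strand transcripts). When `skip_exon_index` is given, that exon
#' is omitted; only internal exons (neither first nor last) may be skipped.
#'
#' @param t A `TranscriptModel`.
#' @param genome Genome as returned by [load_genome()].
#' @param skip_exon_index Optional 1-based index (in transcript orientation)
#'   of one internal exon to omit.
#' @return Nucleotide string of the (skipped) mature transcript.
#' @export
spliced_sequence <- function(t, genome, skip_exon_index = NULL) {
  stopifnot(inherits(t, "TranscriptModel"))
  n <- nrow(t$exons)
  keep <- seq_len(n)
  if (!is.null(skip_exon_index)) {
    si <- as.integer(skip_exon_index)
    if (length(si) != 1L || is.na(si) || si <= 1L || si >= n) {
      stop("skip_exon_index must name an internal exon (2..", n - 1L, ")")
    }
    keep <- keep[keep != si]
  }
  chrseq <- genome[[t$chrom]]
  if (is.null(chrseq)) stop("chromosome not in genome: ", t$chrom)
  pieces <- vapply(keep, function(i) {
    s <- as.character(Biostrings::subseq(chrseq, t$exons$start[i], t$exons$end[i]))
    if (t$strand == "-") revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}
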