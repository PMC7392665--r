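# Junction-read percent-spliced-in (PSI) quantification and tissue-level
# aggregation. PSI of an exon-skipping event is estimated from three junction
# read classes: inc_up (upstream->exon), inc_down (exon->downstream) and exc
# (upstream->downstream, i.e. skipping). Inclusion reads are halved because an
# included exon contributes two junctions:
#
#   PSI = 100 * ((inc_up + inc_down)/2) / ((inc_up + inc_down)/2 + exc)
#
# An event in a sample is "expressed" when inc_up + inc_down + exc >= 20
# supporting reads (configurable); PSI is undefined otherwise.

#' Compute PSI records from a junction count table
#'
#' @param counts data.frame with columns `event_id`, `sample_id`, `inc_up`,
#'   `inc_down`, `exc` (non-negative integers).
#' @param expr_threshold Minimum supporting reads (`inc_up+inc_down+exc`) for
#'   an event to count as expressed in a sample. Default 20.
#' @return data.frame with `event_id`, `sample_id`, `psi` (percent, `NA` when
#'   undefined), `supporting_reads`, `expressed`.
#' @export
compute_psi <- function(counts, expr_threshold = 20L) {
  need <- c("event_id", "sample_id", "inc_up", "inc_down", "exc")
  if (!all(need %in% names(counts))) {
    stop("counts table needs columns: ", paste(need, collapse = ", "))
  }
  cnt <- counts[, c("inc_up", "inc_down", "exc")]
  if (any(unlist(cnt) < 0) || any(unlist(cnt) != floor(unlist(cnt)))) {
    stop("junction counts must be non-negative integers")
  }
  inc_half <- (counts$inc_up + counts$inc_down) / 2
  denom <- inc_half + counts$exc
  psi <- ifelse(denom > 0, 100 * inc_half / denom, NA_real_)
  supporting <- counts$inc_up + counts$inc_down + counts$exc
  expressed <- supporting >= expr_threshold & !is.na(psi)
  data.frame(
    event_id = counts$event_id, sample_id = counts$sample_id,
    psi = ifelse(expressed, psi, NA_real_),
    supporting_reads = supporting, expressed = expressed,
    stringsAsFactors = FALSE
  )
}

#' Aggregate per-sample PSI records into an events x tissues matrix
#'
#' A tissue cell is the arithmetic mean of PSI over the EXPRESSED samples of
#' that tissue; the cell is empty (`NA`) when no sample is expressed.
#'
#' @param records Output of [compute_psi()].
#' @param sample_map data.frame with `sample_id`, `tissue`.
#' @return Numeric matrix (rows = events, columns = tissues) with per-event
#'   MAD weights in attribute `"weight"`.
#' @export
aggregate_by_tissue <- function(records, sample_map) {
  if (!all(c("sample_id", "tissue") %in% names(sample_map))) {
    stop("sample_map needs columns sample_id and tissue")
  }
  unknown <- setdiff(unique(records$sample_id), sample_map$sample_id)
  if (length(unknown)) {
    stop("sample id(s) missing from sample_map: ",
         paste(unknown, collapse = ", "))
  }
  records$tissue <- sample_map$tissue[match(records$sample_id,
                                            sample_map$sample_id)]
  events <- sort(unique(records$event_id))
  tissues <- sort(unique(sample_map$tissue))
  m <- matrix(NA_real_, nrow = length(events), ncol = length(tissues),
              dimnames = list(events, tissues))
  expr <- records[records$expressed, , drop = FALSE]
  if (nrow(expr)) {
    agg <- stats::aggregate(psi ~ event_id + tissue, data = expr, FUN = mean)
    m[cbind(match(agg$event_id, events), match(agg$tissue, tissues))] <- agg$psi
  }
  w <- apply(m, 1L, function(row) stats::mad(row, na.rm = TRUE))
  attr(m, "weight") <- w
  m
}

#' Call events as alternatively spliced across tissues
#'
#' An event is alternative when its PSI is below `psi_cutoff` in at least one
#' tissue. Events with no non-empty cell are `NA` ("not testable").
#'
#' @param m Tissue matrix from [aggregate_by_tissue()].
#' @param psi_cutoff PSI threshold (strict `<`), default 90.
#' @return Named logical vector per event (`NA` = not testable).
#' @export
call_alternative <- function(m, psi_cutoff = 90) {
  apply(m, 1L, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return(NA)
    any(row < psi_cutoff)
  })
}

#' Per-event PSI summary statistics across tissues
#'
#' @param m Tissue matrix from [aggregate_by_tissue()].
#' @return data.frame with `event_id`, `PSI_MIN`, `PSI_MEDIAN`, `PSI_MEAN`,
#'   `PSI_MAX`, `n_tissues` (non-empty cells only). Events with no non-empty
#'   cell are dropped.
#' @export
psi_summary <- function(m) {
  rows <- lapply(rownames(m), function(ev) {
    v <- m[ev, ][!is.na(m[ev, ])]
    if (!length(v)) return(NULL)
    data.frame(event_id = ev, PSI_MIN = min(v), PSI_MEDIAN = stats::median(v),
               PSI_MEAN = mean(v), PSI_MAX = max(v), n_tissues = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Weighted Pearson correlation between two vectors with observation weights.
.weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cov <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) stop("zero weighted variance in tissue column")
  cov / sqrt(vx * vy)
}

#' Tissue-by-tissue distance matrix from PSI profiles
#'
#' Distance between two tissues is 1 minus the weighted Pearson correlation
#' of their PSI columns, using each event's median absolute deviation (MAD)
#' across tissues as its weight so that more variable exons have greater
#' influence. Events with any empty cell are dropped (reported via
#' `message()`).
#'
#' @param m Tissue matrix from [aggregate_by_tissue()].
#' @return Symmetric tissues x tissues matrix with zero diagonal, entries in
#'   `[0, 2]`.
#' @export
tissue_distance <- function(m) {
  complete <- stats::complete.cases(m)
  if (sum(!complete) > 0L) {
    message("tissue_distance: dropping ", sum(!complete),
            " event(s) with empty cells")
  }
  mm <- m[complete, , drop = FALSE]
  if (nrow(mm) < 2L) stop("need >= 2 complete events for a distance matrix")
  w <- apply(mm, 1L, stats::mad)
  if (sum(w) <= 0) stop("zero total weight: all events are constant across tissues")
  k <- ncol(mm)
  d <- matrix(0, k, k, dimnames = list(colnames(mm), colnames(mm)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      d[i, j] <- d[j, i] <- 1 - .weighted_pearson(mm[, i], mm[, j], w)
    }
  }
  d
}

#' Select target and background exon sets for RBP motif discovery
#'
#' Operating on a matrix over differentiation stages, restricted to events
#' expressed (non-empty) in every stage: the background set contains events
#' constitutively spliced in (PSI > `hi` in every stage) or constitutively
#' spliced out (PSI < `lo` in every stage); the target set contains events
#' with a PSI range above `delta` between any two stages. The two sets are
#' disjoint by construction.
#'
#' @param m Stage matrix from [aggregate_by_tissue()].
#' @param hi,lo,delta Thresholds; defaults 90, 20 and 50.
#' @return List with character vectors `target` and `background`, plus
#'   `expressed_all` (ids of events expressed in every stage).
#' @export
select_motif_sets <- function(m, hi = 90, lo = 20, delta = 50) {
  complete <- stats::complete.cases(m)
  mm <- m[complete, , drop = FALSE]
  const_in <- apply(mm, 1L, function(r) all(r > hi))
  const_out <- apply(mm, 1L, function(r) all(r < lo))
  rng <- apply(mm, 1L, function(r) max(r) - min(r))
  background <- rownames(mm)[const_in | const_out]
  target <- setdiff(rownames(mm)[rng > delta], background)
  list(target = target, background = background,
       expressed_all = rownames(mm))
}

#' Write exon +/- flanking intron FASTAs for the target and background sets
#'
#' Emits the skipped-exon sequence with `flank` bases of upstream and
#' downstream intron, in transcript orientation, for use by external motif
#' discovery tools.
#'
#' @param sets Output of [select_motif_sets()].
#' @param events Candidate/event table carrying `event_id` (or
#'   `transcript_id`), `chrom`, `strand`, `exon_start`, `exon_end`.
#' @param genome Genome from [load_genome()].
#' @param out_prefix Path prefix; writes `<prefix>_TARGET.fa` and
#'   `<prefix>_BACKGROUND.fa`.
#' @param flank Intronic flank length in bases (default 50).
#' @return Invisibly, the two file paths.
#' @export
write_motif_fastas <- function(sets, events, genome, out_prefix, flank = 50L) {
  ids <- if ("event_id" %in% names(events)) events$event_id else events$transcript_id
  get_seq <- function(sel_ids) {
    rows <- events[match(sel_ids, ids), , drop = FALSE]
    seqs <- vapply(seq_len(nrow(rows)), function(r) {
      lo <- min(rows$exon_start[r], rows$exon_end[r]) - flank
      hi <- max(rows$exon_start[r], rows$exon_end[r]) + flank
      chr <- genome[[rows$chrom[r]]]
      lo <- max(1L, lo); hi <- min(length(chr), hi)
      s <- as.character(Biostrings::subseq(chr, lo, hi))
      if (rows$strand[r] == "-") revcomp(s) else s
    }, character(1))
    stats::setNames(seqs, sel_ids)
  }
  tfa <- paste0(out_prefix, "_TARGET.fa")
  bfa <- paste0(out_prefix, "_BACKGROUND.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(get_seq(sets$target)), tfa)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(get_seq(sets$background)), bfa)
  invisible(c(tfa, bfa))
}
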