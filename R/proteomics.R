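# Frameshift-augmented protein search database, in-silico tryptic digestion,
# proteotypic-peptide flagging and IP-MS heavy/light enrichment calls.

#' Build a frameshift-augmented protein database
#'
#' For every deduplicated candidate, appends a record consisting of the
#' canonical protein prefix up to the divergence point plus the new
#' C-terminus. Accessions are suffixed deterministically with
#' `_fs<exon index>`; frameshift records whose sequence equals an already
#' present record are collapsed (reported via `message()`).
#'
#' @param canonical Named character vector or [Biostrings::AAStringSet] of
#'   canonical protein sequences; names are accessions. Candidates are
#'   matched by `transcript_id`.
#' @param candidates Passing candidate table (needs `transcript_id`,
#'   `exon_index_skipped`, `divergence_point`, `new_cterm_aa`).
#' @param fasta Optional path; when given the full database is written as
#'   FASTA.
#' @return data.frame with `accession`, `sequence`, `origin`
#'   (`canonical`/`predicted_frameshift`), `source_event` and `fs_from`
#'   (1-based position where the novel segment starts; `NA` for canonical
#'   records).
#' @export
build_fs_database <- function(canonical, candidates, fasta = NULL) {
  canonical <- stats::setNames(as.character(canonical), names(canonical))
  if (is.null(names(canonical)) || any(!nzchar(names(canonical)))) {
    stop("canonical sequences must be named by accession")
  }
  db <- data.frame(
    accession = names(canonical), sequence = unname(canonical),
    origin = "canonical", source_event = NA_character_,
    fs_from = NA_integer_, stringsAsFactors = FALSE
  )
  collapsed <- 0L
  for (r in seq_len(nrow(candidates))) {
    tid <- candidates$transcript_id[r]
    if (!tid %in% names(canonical)) {
      stop("candidate references unknown canonical accession: ", tid)
    }
    div <- candidates$divergence_point[r]
    prefix <- substring(canonical[[tid]], 1L, div - 1L)
    seqaa <- paste0(prefix, candidates$new_cterm_aa[r])
    if (seqaa %in% db$sequence) { collapsed <- collapsed + 1L; next }
    db <- rbind(db, data.frame(
      accession = sprintf("%s_fs%d", tid, candidates$exon_index_skipped[r]),
      sequence = seqaa, origin = "predicted_frameshift",
      source_event = sprintf("%s:exon%d", tid, candidates$exon_index_skipped[r]),
      fs_from = div, stringsAsFactors = FALSE
    ))
  }
  if (collapsed > 0L) {
    message("build_fs_database: collapsed ", collapsed,
            " frameshift record(s) identical to existing sequences")
  }
  if (anyDuplicated(db$accession)) stop("duplicate accessions in database")
  if (!is.null(fasta)) {
    aa <- Biostrings::AAStringSet(db$sequence)
    names(aa) <- db$accession
    Biostrings::writeXStringSet(aa, fasta)
  }
  db
}

# 0-based cleavage sites of trypsin: C-terminal to K or R, not before P.
.tryptic_sites <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 2L) return(integer())
  which(chars[-n] %in% c("K", "R") & chars[-1L] != "P")
}

#' In-silico tryptic digestion of one protein
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and
#' enumerates all peptides with 0..`max_missed` internal missed cleavage
#' sites and length at least `min_len`.
#'
#' @param sequence Protein sequence (single string).
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param min_len Minimum peptide length (default 6).
#' @return data.frame with `peptide`, `start`, `end` (1-based positions in
#'   the protein) and `missed_cleavages`.
#' @export
tryptic_digest <- function(sequence, max_missed = 2L, min_len = 6L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  sites <- .tryptic_sites(sequence)
  bounds <- c(0L, sites, nchar(sequence))   # fragment boundaries
  nfrag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      if (e - s + 1L < min_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = substring(sequence, s, e), start = s, end = e,
        missed_cleavages = m, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed_cleavages = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Digest a database and flag proteotypic frameshift peptides
#'
#' Digests every frameshift record of the database, keeps peptides that
#' overlap the novel C-terminal segment by at least one residue, assigns
#' each peptide its parent records (every database entry containing the
#' peptide as a substring) and flags peptides with exactly one parent as
#' proteotypic.
#'
#' @param database Database from [build_fs_database()].
#' @param max_missed,min_len Digestion parameters, see [tryptic_digest()].
#' @return data.frame with `peptide`, `source_accession`,
#'   `missed_cleavages`, `maps_to_fs_cterm`, `n_parents`, `parents`
#'   (`;`-separated accessions), `proteotypic`; summary counts in attribute
#'   `"summary"` (fs-mapping peptides, proteotypic fs peptides, distinct fs
#'   isoforms unambiguously identified).
#' @export
flag_proteotypic <- function(database, max_missed = 2L, min_len = 6L) {
  fs <- database[database$origin == "predicted_frameshift", , drop = FALSE]
  peps <- list()
  for (r in seq_len(nrow(fs))) {
    dig <- tryptic_digest(fs$sequence[r], max_missed, min_len)
    if (!nrow(dig)) next
    dig$maps_to_fs_cterm <- dig$end >= fs$fs_from[r]
    dig <- dig[dig$maps_to_fs_cterm, , drop = FALSE]
    if (!nrow(dig)) next
    dig$source_accession <- fs$accession[r]
    peps[[length(peps) + 1L]] <- dig
  }
  if (!length(peps)) stop("no frameshift-mapping peptides in database")
  peps <- do.call(rbind, peps)
  peps <- peps[!duplicated(paste(peps$peptide, peps$source_accession)), ,
               drop = FALSE]
  uniq <- unique(peps$peptide)
  parent_list <- lapply(uniq, function(p) {
    database$accession[grepl(p, database$sequence, fixed = TRUE)]
  })
  names(parent_list) <- uniq
  peps$n_parents <- vapply(parent_list[peps$peptide], length, integer(1))
  peps$parents <- vapply(parent_list[peps$peptide], paste, character(1),
                         collapse = ";")
  peps$proteotypic <- peps$n_parents == 1L
  rownames(peps) <- NULL
  uniq_rows <- peps[!duplicated(peps$peptide), , drop = FALSE]
  attr(peps, "summary") <- c(
    fs_mapping_peptides = nrow(uniq_rows),
    proteotypic_fs_peptides = sum(uniq_rows$proteotypic),
    fs_isoforms_identified = length(unique(
      unlist(parent_list[uniq_rows$peptide[uniq_rows$proteotypic]])))
  )
  peps
}

# Monoisotopic residue masses (Da); water and proton for peptide m/z.
.MONO_MASS <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
                V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
                I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
                K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
                F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.MASS_WATER <- 18.010565
.MASS_PROTON <- 1.007276
.MASS_CARBAMIDOMETHYL <- 57.02146

#' Monoisotopic peptide m/z
#'
#' @param peptide Peptide sequence.
#' @param charge Charge state (default 2).
#' @param carbamidomethyl Apply fixed carbamidomethylation of cysteines
#'   (default `TRUE`).
#' @return m/z value.
#' @export
peptide_mz <- function(peptide, charge = 2L, carbamidomethyl = TRUE) {
  chars <- strsplit(toupper(peptide), "")[[1]]
  if (!all(chars %in% names(.MONO_MASS))) {
    stop("peptide contains non-standard residues")
  }
  m <- sum(.MONO_MASS[chars]) + .MASS_WATER
  if (carbamidomethyl) m <- m + .MASS_CARBAMIDOMETHYL * sum(chars == "C")
  (m + charge * .MASS_PROTON) / charge
}

#' Call IP-MS enrichment from heavy/light ratio tables
#'
#' Each replicate column is normalized by its median; a protein is enriched
#' when its normalized ratio exceeds `threshold` in EVERY replicate.
#' Proteins matching an exclusion pattern (by default tubulins and heat-shock
#' proteins, which are frequent pulldown false positives) are never called
#' enriched; proteins with a missing replicate are reported as not
#' quantified.
#'
#' @param ratios data.frame with a `protein` column and one numeric column
#'   per replicate.
#' @param threshold Enrichment threshold on the normalized ratio
#'   (default 1.5).
#' @param exclusions Regular expression of excluded protein families
#'   (case-insensitive); `NULL` disables exclusion.
#' @return data.frame with `protein`, normalized replicate columns,
#'   `quantified`, `excluded`, `enriched`, `reason`.
#' @export
call_ip_enrichment <- function(ratios, threshold = 1.5,
                               exclusions = "tubulin|^tub|hsp|heat shock") {
  stopifnot("protein" %in% names(ratios))
  repcols <- setdiff(names(ratios), "protein")
  if (length(repcols) < 2L) stop("need >= 2 replicate columns")
  norm <- ratios
  for (cc in repcols) {
    med <- stats::median(ratios[[cc]], na.rm = TRUE)
    if (!is.finite(med) || med <= 0) stop("non-positive median in replicate ", cc)
    norm[[cc]] <- ratios[[cc]] / med
  }
  quantified <- stats::complete.cases(norm[, repcols, drop = FALSE])
  excluded <- if (is.null(exclusions)) rep(FALSE, nrow(norm)) else
    grepl(exclusions, norm$protein, ignore.case = TRUE)
  above <- apply(norm[, repcols, drop = FALSE] > threshold, 1L, all)
  enriched <- quantified & !excluded & above
  enriched[!quantified] <- FALSE
  reason <- ifelse(!quantified, "not_quantified",
            ifelse(excluded, "excluded_family",
            ifelse(enriched, "enriched", "below_threshold")))
  norm$quantified <- quantified
  norm$excluded <- excluded
  norm$enriched <- enriched
  norm$reason <- reason
  norm
}
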