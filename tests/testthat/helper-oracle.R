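# Independent brute-force oracles used to cross-check the package
# implementation. These deliberately avoid the package's own code paths:
# naive string operations, seqinr translation, minimal GTF field splitting.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}

# Translate from `from` to the first stop (stop excluded), via seqinr.
oracle_translate <- function(s, from = 1L) {
  sub <- substring(toupper(s), from)
  n <- nchar(sub) - nchar(sub) %% 3L
  if (n < 3L) return("")
  aa <- seqinr::translate(seqinr::s2c(substr(sub, 1L, n)))
  stops <- which(aa == "*")
  if (length(stops)) aa <- aa[seq_len(stops[1L] - 1L)]
  paste(aa, collapse = "")
}

# Minimal GTF reader: tab splitting plus one regex per attribute.
oracle_read_gtf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    type = vapply(parts, `[[`, "", 3L),
    start = as.integer(vapply(parts, `[[`, "", 4L)),
    end = as.integer(vapply(parts, `[[`, "", 5L)),
    strand = vapply(parts, `[[`, "", 7L),
    attrs = vapply(parts, `[[`, "", 9L),
    stringsAsFactors = FALSE
  )
  df$tid <- sub('.*transcript_id "([^"]+)".*', "\\1", df$attrs)
  df
}

# Naive per-exon substring + join (+ reverse complement) mRNA assembly and
# brute-force alternative C-terminus of the penultimate-exon-skipped isoform.
oracle_candidate <- function(gtfdf, chromseqs, tid) {
  rows <- gtfdf[gtfdf$tid == tid, , drop = FALSE]
  ex <- rows[rows$type == "exon", , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  strand <- ex$strand[1L]
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  build <- function(df) {
    paste(vapply(seq_len(nrow(df)), function(i) {
      s <- substr(chromseqs[[df$chrom[i]]], df$start[i], df$end[i])
      if (strand == "-") oracle_revcomp(s) else s
    }, character(1)), collapse = "")
  }
  n <- nrow(ex)
  mrna_full <- build(ex)
  mrna_skip <- build(ex[-(n - 1L), , drop = FALSE])
  cds <- rows[rows$type == "CDS", , drop = FALSE]
  atg_g <- if (strand == "+") min(cds$start) else max(cds$end)
  # transcript coordinate of the start codon
  pos <- 0L
  for (i in seq_len(n)) {
    if (atg_g >= ex$start[i] && atg_g <= ex$end[i]) {
      off <- if (strand == "+") atg_g - ex$start[i] + 1L
             else ex$end[i] - atg_g + 1L
      pos <- pos + off
      break
    }
    pos <- pos + ex$end[i] - ex$start[i] + 1L
  }
  can <- strsplit(oracle_translate(mrna_full, pos), "")[[1L]]
  new <- strsplit(oracle_translate(mrna_skip, pos), "")[[1L]]
  L <- min(length(can), length(new))
  diffs <- if (L > 0L) which(can[seq_len(L)] != new[seq_len(L)]) else integer()
  d <- if (length(diffs)) diffs[1L] else L + 1L
  if (d > length(new)) "" else paste(new[d:length(new)], collapse = "")
}

# Brute-force overlapping motif count via regex lookahead.
oracle_scan <- function(seq, classes) {
  pat <- paste(vapply(classes, function(cls) {
    if (is.null(cls)) "." else paste0("[", paste(cls, collapse = ""), "]")
  }, character(1)), collapse = "")
  res <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1L]]
  if (length(res) == 1L && res[1L] == -1L) 0L else length(res)
}

# Toy study written to a temp dir, loaded back through the package readers.
make_toy_fixture <- function(n_per_class = 2L, seed = 0L, ...) {
  toy <- generate_toy_genome(n_per_class = n_per_class, seed = seed, ...)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_toy_data(toy, dir)
  genome <- load_genome(file.path(dir, "genome.fa"))
  tx <- suppressMessages(load_annotation(file.path(dir, "annotation.gtf"),
                                         genome))
  list(toy = toy, dir = dir, genome = genome, tx = tx)
}
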