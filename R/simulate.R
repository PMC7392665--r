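# Synthetic study generator: toy genomes with planted penultimate-exon
# skipping truth, binomial junction counts at planted PSI, and half-life
# tables with a planted P-rich effect.
#
# Gene construction works backwards from amino-acid truths. The new-frame
# content of the last exon is chosen as an explicit AA string and
# reverse-translated with a codon table in which no codon ends in T; the
# out-of-frame (canonical, offset +2) reading of such codon runs can then
# never hit a stop codon, except where one T-ending codon is planted
# deliberately to create the canonical stop at a chosen position. This gives
# exact control over both aa_gained (number of new-frame residues) and
# aa_beyond_stop (residues whose first codon base lies 3' of the planted
# canonical stop).

.GENERATOR_VERSION <- "utr3frame-toygen-1"

# One codon per AA, none ending in T, none a stop codon.
.CODON_NOT <- c(A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC",
                Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
                L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
                S = "AGC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG")

.rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.rand_intron <- function() paste0("GT", .rand_dna(sample(50:80, 1L)), "AG")

.sample_aa <- function(n, prich) {
  others <- setdiff(.AA20, "P")
  out <- ifelse(stats::runif(n) < prich, "P",
                sample(others, n, replace = TRUE))
  out
}

# Exon plan of one gene in FORWARD (coding-strand) gene coordinates:
# exon sequences plus per-exon CDS intervals and the stop-codon location.
# class "Ultimate"-geometry genes (Ultimate, Penulti_short, fail_* controls)
# plant canonical stop s codons into the last exon's out-of-frame reading,
# with s = g - b - 2.
.plan_ultimate_like <- function(g, b, prich, a, m) {
  s <- g - b - 2L
  stopifnot(s >= 0L, g >= 2L)
  aa <- .sample_aa(g, prich)
  if (aa[1L] == "E") aa[1L] <- "A"   # must differ from canonical E2 codons (E)
  aa[s + 1L] <- "P"; aa[s + 2L] <- "K"
  codons <- .CODON_NOT[aa]
  codons[s + 1L] <- "CCT"            # T-ending P codon: plants canonical stop
  codons[s + 2L] <- "AAA"            # ..completed by AA -> TAA at offset +2
  utr5 <- sample(10:25, 1L)
  e1 <- paste0(.rand_dna(utr5), "ATG",
               paste(.CODON_NOT[.sample_aa(a, 0.05)], collapse = ""))
  e2 <- paste0(strrep("GAG", m), "C")          # length 3m+1: frameshifting
  e3 <- paste0(paste(codons, collapse = ""), "TAA", .rand_dna(24L))
  list(
    exons = c(e1, e2, e3),
    cds = list(c(utr5 + 1L, nchar(e1)), c(1L, 3L * m + 1L), c(1L, 3L * s + 2L)),
    stop = c(3L, 3L * s + 3L, 3L * s + 5L),
    new_cterm = paste(aa, collapse = ""), aa_gained = g, aa_beyond = b
  )
}

.plan_penultimate <- function(g, prich, a, m) {
  aa <- .sample_aa(g, prich)
  if (aa[1L] == "E") aa[1L] <- "A"
  utr5 <- sample(10:25, 1L)
  e1 <- paste0(.rand_dna(utr5), "ATG",
               paste(.CODON_NOT[.sample_aa(a, 0.05)], collapse = ""))
  e2 <- paste0(strrep("GAG", m), "TAA", .rand_dna(8L))  # stop inside penultimate
  e3 <- paste0(paste(.CODON_NOT[aa], collapse = ""), "TAA", .rand_dna(24L))
  list(
    exons = c(e1, e2, e3),
    cds = list(c(utr5 + 1L, nchar(e1)), c(1L, 3L * m), NULL),
    stop = c(2L, 3L * m + 1L, 3L * m + 3L),
    new_cterm = paste(aa, collapse = ""), aa_gained = g, aa_beyond = g
  )
}

# Frame-preserving / non-extending comparison genes built by cutting one
# continuous coding sequence at chosen exon lengths (the canonical frame is
# unaffected by where the cuts fall).
.plan_straddle <- function(cut_lens, n_aa = 40L) {
  coding <- paste0("ATG", paste(.CODON_NOT[.sample_aa(n_aa, 0.05)],
                                collapse = ""))
  stopifnot(sum(cut_lens) <= nchar(coding))
  utr5 <- sample(10:25, 1L)
  bounds <- cumsum(cut_lens)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, nchar(coding))
  pieces <- substring(coding, starts, ends)
  k <- length(pieces)
  exons <- pieces
  exons[1L] <- paste0(.rand_dna(utr5), pieces[1L])
  exons[k] <- paste0(pieces[k], "TAA", .rand_dna(20L))
  cds <- vector("list", k)
  cds[[1L]] <- c(utr5 + 1L, nchar(exons[1L]))
  for (i in seq_len(k)[-1L]) cds[[i]] <- c(1L, nchar(pieces[i]))
  list(
    exons = exons,
    cds = cds,
    stop = c(k, nchar(pieces[k]) + 1L, nchar(pieces[k]) + 3L),
    new_cterm = NA_character_, aa_gained = NA_integer_, aa_beyond = NA_integer_
  )
}

.plan_for_class <- function(class) {
  a <- sample(3:8, 1L); m <- sample(2:4, 1L)
  switch(class,
    Ultimate = {
      g <- sample(30:60, 1L); b <- sample(10:(g - 2L), 1L)
      .plan_ultimate_like(g, b, prich = 0.30, a, m)
    },
    Penultimate = .plan_penultimate(sample(25:50, 1L), prich = 0.05, a, m),
    Penulti_short = .plan_ultimate_like(g = 12L, b = 0L, prich = 0.10, a, m = 3L),
    fail_gained = .plan_ultimate_like(g = 19L, b = 10L, prich = 0.10, a, m),
    fail_beyond = .plan_ultimate_like(g = 25L, b = 9L, prich = 0.10, a, m),
    Penulti_fp = .plan_straddle(c(33L, 30L)),
    Internal_fp = .plan_straddle(c(33L, 30L, 30L)),
    Internal_fs = .plan_straddle(c(33L, 31L, 30L)),
    stop("unknown geometry class: ", class)
  )
}

# Lay one planned gene out with introns, producing the forward gene sequence
# and per-isoform GTF features in forward gene coordinates. A second isoform,
# when requested, extends exon 1 by extra 5'UTR: identical dedup 5-tuple.
.layout_gene <- function(gene_id, plan, n_isoforms, ext5_len = 12L) {
  k <- length(plan$exons)
  introns <- if (k > 1L) vapply(seq_len(k - 1L), function(i) .rand_intron(),
                                character(1)) else character()
  ext5 <- .rand_dna(ext5_len)
  seq <- ext5
  exon_off <- matrix(0L, nrow = k, ncol = 2L)  # forward offsets of exons
  for (i in seq_len(k)) {
    exon_off[i, 1L] <- nchar(seq) + 1L
    seq <- paste0(seq, plan$exons[i])
    exon_off[i, 2L] <- nchar(seq)
    if (i < k) seq <- paste0(seq, introns[i])
  }
  feats <- list()
  add <- function(type, fs, fe, tid) {
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, fstart = fs, fend = fe, transcript_id = tid,
      stringsAsFactors = FALSE)
  }
  for (iso in seq_len(n_isoforms)) {
    tid <- sprintf("%s.t%d", gene_id, iso)
    for (i in seq_len(k)) {
      es <- if (i == 1L && iso == 2L) 1L else exon_off[i, 1L]
      add("exon", es, exon_off[i, 2L], tid)
      if (!is.null(plan$cds[[i]])) {
        add("CDS", exon_off[i, 1L] + plan$cds[[i]][1L] - 1L,
            exon_off[i, 1L] + plan$cds[[i]][2L] - 1L, tid)
      }
    }
    add("stop_codon", exon_off[plan$stop[1L], 1L] + plan$stop[2L] - 1L,
        exon_off[plan$stop[1L], 1L] + plan$stop[3L] - 1L, tid)
  }
  list(seq = seq, features = do.call(rbind, feats))
}

.gtf_attr <- function(gene_id, tid, biotype) {
  sprintf(paste0('gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; ',
                 'transcript_biotype "%s";'), gene_id, tid, biotype, biotype)
}

# Core generator over an explicit gene spec table.
.generate_from_specs <- function(specs, seed, include_decoys = TRUE) {
  set.seed(seed)
  chroms <- c("toy1", "toy2")
  chrom_seq <- stats::setNames(rep("", length(chroms)), chroms)
  gtf <- character()
  truth <- list()
  for (r in seq_len(nrow(specs))) {
    gene_id <- specs$gene_id[r]
    strand <- specs$strand[r]
    plan <- .plan_for_class(specs$class[r])
    lay <- .layout_gene(gene_id, plan, specs$n_isoforms[r])
    chrom <- chroms[(r - 1L) %% length(chroms) + 1L]
    spacer <- .rand_dna(40L)
    gstart <- nchar(chrom_seq[[chrom]]) + nchar(spacer) + 1L
    glen <- nchar(lay$seq)
    placed <- if (strand == "+") lay$seq else revcomp(lay$seq)
    chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]], spacer, placed)
    f <- lay$features
    if (strand == "+") {
      f$gstart <- gstart + f$fstart - 1L
      f$gend <- gstart + f$fend - 1L
    } else {
      f$gstart <- gstart + glen - f$fend
      f$gend <- gstart + glen - f$fstart
    }
    attr_str <- .gtf_attr(gene_id, f$transcript_id, "protein_coding")
    gtf <- c(gtf, sprintf("%s\ttoygen\t%s\t%d\t%d\t.\t%s\t.\t%s",
                          chrom, f$type, f$gstart, f$gend, strand, attr_str))
    truth[[r]] <- data.frame(
      gene_id = gene_id, transcript_id = sprintf("%s.t1", gene_id),
      class = specs$class[r], strand = strand, chrom = chrom,
      n_isoforms = specs$n_isoforms[r],
      aa_gained = plan$aa_gained, aa_beyond_stop = plan$aa_beyond,
      new_cterm = plan$new_cterm,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  truth$passes <- truth$class %in% c("Ultimate", "Penultimate") &
    !is.na(truth$aa_gained) & truth$aa_gained >= 20L &
    !is.na(truth$aa_beyond_stop) & truth$aa_beyond_stop >= 10L
  if (include_decoys) {
    # one non-coding transcript and one coding transcript without an
    # annotated stop codon: both must be dropped by the annotation loader
    for (chrom in chroms) {
      base <- nchar(chrom_seq[[chrom]])
      chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]], .rand_dna(200L))
      if (chrom == chroms[1L]) {
        gtf <- c(gtf,
          sprintf("%s\ttoygen\texon\t%d\t%d\t.\t+\t.\t%s", chrom,
                  base + 10L, base + 60L,
                  .gtf_attr("DECOY_LNC", "DECOY_LNC.t1", "lincRNA")),
          sprintf("%s\ttoygen\texon\t%d\t%d\t.\t+\t.\t%s", chrom,
                  base + 100L, base + 150L,
                  .gtf_attr("DECOY_LNC", "DECOY_LNC.t1", "lincRNA")))
      } else {
        at <- .gtf_attr("DECOY_NOSTOP", "DECOY_NOSTOP.t1", "protein_coding")
        gtf <- c(gtf,
          sprintf("%s\ttoygen\texon\t%d\t%d\t.\t+\t.\t%s", chrom,
                  base + 10L, base + 60L, at),
          sprintf("%s\ttoygen\texon\t%d\t%d\t.\t+\t.\t%s", chrom,
                  base + 100L, base + 150L, at),
          sprintf("%s\ttoygen\tCDS\t%d\t%d\t.\t+\t.\t%s", chrom,
                  base + 20L, base + 60L, at))
      }
    }
  }
  genome <- Biostrings::DNAStringSet(chrom_seq)
  list(genome = genome, gtf = gtf, truth = truth)
}

#' Generate a toy genome with planted exon-skipping truth
#'
#' Plants `n_per_class` genes (alternating strands) for each geometry class
#' `Ultimate`, `Penultimate`, `Penulti_fp`, `Internal_fp`, `Internal_fs`,
#' `Penulti_short`, plus two fail-filter controls (`fail_gained`:
#' aa_gained = 19; `fail_beyond`: aa_beyond_stop = 9). Ultimate and
#' Penultimate genes carry two transcript isoforms that differ only by
#' 5'UTR extent, so the discovery stage must collapse them to one event
#' each. The expected passing set is therefore exactly the Ultimate and
#' Penultimate genes. Each passing event also receives a planted per-tissue
#' PSI profile (half of them skipped, PSI 40, in one tissue; the rest
#' constitutive at PSI 95).
#'
#' @param n_per_class Genes per geometry class (default 5).
#' @param seed Integer seed; the same seed reproduces byte-identical
#'   outputs.
#' @param tissues Tissue names for the PSI truth (default 5 mouse-style
#'   tissues).
#' @param include_decoys Also plant a non-coding transcript and a coding
#'   transcript without a stop codon (both must be dropped on loading).
#' @return List of class `toy_study`: `genome` (DNAStringSet), `gtf`
#'   (character lines), `truth` (per-gene planted values), `psi_truth`
#'   (event x tissue planted PSI, long), `seed`.
#' @export
generate_toy_genome <- function(n_per_class = 5L, seed = 0L,
                                tissues = c("brain", "liver", "heart",
                                            "kidney", "muscle"),
                                include_decoys = TRUE) {
  stopifnot(n_per_class >= 1L)
  classes <- c(Ultimate = "ULT", Penultimate = "PEN", Penulti_fp = "PFP",
               Internal_fp = "IFP", Internal_fs = "IFS", Penulti_short = "PSH",
               fail_gained = "FGA", fail_beyond = "FBE")
  specs <- do.call(rbind, lapply(names(classes), function(cl) {
    data.frame(
      gene_id = sprintf("G%s%02d", classes[[cl]], seq_len(n_per_class)),
      class = cl,
      strand = rep(c("+", "-"), length.out = n_per_class),
      n_isoforms = if (cl %in% c("Ultimate", "Penultimate")) 2L else 1L,
      stringsAsFactors = FALSE
    )
  }))
  out <- .generate_from_specs(specs, seed, include_decoys)
  passing <- out$truth$gene_id[out$truth$passes]
  psi <- do.call(rbind, lapply(seq_along(passing), function(i) {
    base <- rep(95, length(tissues))
    alternative <- i %% 2L == 1L
    if (alternative) base[(i %% length(tissues)) + 1L] <- 40
    data.frame(event_id = passing[i], tissue = tissues, psi = base,
               alternative = alternative, stringsAsFactors = FALSE)
  }))
  structure(c(out, list(psi_truth = psi, seed = seed)), class = "toy_study")
}

#' Generate many randomized extension candidates (for property testing)
#'
#' Plants `n` single-isoform genes of random `Ultimate`/`Penultimate`
#' geometry with randomized gain parameters (`aa_gained` 2..80,
#' `aa_beyond_stop` 0..`aa_gained`-2 for Ultimate) and random strands.
#'
#' @param n Number of genes.
#' @param seed Integer seed.
#' @return `toy_study` list (without PSI truth).
#' @export
generate_candidate_genes <- function(n, seed = 0L) {
  set.seed(seed)
  cls <- sample(c("Ultimate", "Penultimate"), n, replace = TRUE)
  specs <- data.frame(
    gene_id = sprintf("R%04d", seq_len(n)), class = cls,
    strand = sample(c("+", "-"), n, replace = TRUE),
    n_isoforms = 1L, stringsAsFactors = FALSE
  )
  out <- .generate_random_specs(specs, seed)
  structure(c(out, list(seed = seed)), class = "toy_study")
}

# Like .generate_from_specs but with per-gene randomized gain parameters.
.generate_random_specs <- function(specs, seed) {
  set.seed(seed)
  chrom_seq <- stats::setNames(rep("", 2L), c("toy1", "toy2"))
  gtf <- character()
  truth <- list()
  for (r in seq_len(nrow(specs))) {
    gene_id <- specs$gene_id[r]
    strand <- specs$strand[r]
    a <- sample(2:8, 1L); m <- sample(1:4, 1L)
    plan <- if (specs$class[r] == "Ultimate") {
      g <- sample(2:80, 1L)
      b <- if (g > 2L) sample(0:(g - 2L), 1L) else 0L
      .plan_ultimate_like(g, b, prich = stats::runif(1, 0, 0.4), a, max(2L, m))
    } else {
      .plan_penultimate(sample(2:80, 1L), prich = stats::runif(1, 0, 0.4), a, m)
    }
    lay <- .layout_gene(gene_id, plan, 1L)
    chrom <- c("toy1", "toy2")[(r - 1L) %% 2L + 1L]
    spacer <- .rand_dna(30L)
    gstart <- nchar(chrom_seq[[chrom]]) + nchar(spacer) + 1L
    glen <- nchar(lay$seq)
    placed <- if (strand == "+") lay$seq else revcomp(lay$seq)
    chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]], spacer, placed)
    f <- lay$features
    if (strand == "+") {
      f$gstart <- gstart + f$fstart - 1L
      f$gend <- gstart + f$fend - 1L
    } else {
      f$gstart <- gstart + glen - f$fend
      f$gend <- gstart + glen - f$fstart
    }
    gtf <- c(gtf, sprintf("%s\ttoygen\t%s\t%d\t%d\t.\t%s\t.\t%s",
                          chrom, f$type, f$gstart, f$gend, strand,
                          .gtf_attr(gene_id, f$transcript_id, "protein_coding")))
    truth[[r]] <- data.frame(
      gene_id = gene_id, transcript_id = sprintf("%s.t1", gene_id),
      class = specs$class[r], strand = strand, chrom = chrom, n_isoforms = 1L,
      aa_gained = plan$aa_gained, aa_beyond_stop = plan$aa_beyond,
      new_cterm = plan$new_cterm, stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  truth$passes <- truth$aa_gained >= 20L & truth$aa_beyond_stop >= 10L
  list(genome = Biostrings::DNAStringSet(chrom_seq), gtf = gtf, truth = truth)
}

#' Simulate junction read counts at planted PSI
#'
#' For each event, tissue and replicate, the number of inclusion molecules
#' among `depth` observed is binomial at the planted PSI; each inclusion
#' molecule contributes one read to each of the two inclusion junctions and
#' each exclusion molecule one read to the skipping junction:
#' `exc ~ Binomial(depth, 1 - psi/100)`, `inc_up = inc_down = depth - exc`.
#'
#' @param psi_truth data.frame with `event_id`, `tissue`, `psi` (and
#'   optionally a per-event `depth` column overriding `depth`).
#' @param depth Molecules sampled per event and sample (default 200).
#' @param samples_per_tissue Replicates per tissue (default 3).
#' @param seed Integer seed.
#' @return List with `counts` (event_id, sample_id, inc_up, inc_down, exc)
#'   and `sample_map` (sample_id, tissue).
#' @export
simulate_junction_counts <- function(psi_truth, depth = 200L,
                                     samples_per_tissue = 3L, seed = 0L) {
  stopifnot(all(psi_truth$psi >= 0 & psi_truth$psi <= 100))
  set.seed(seed)
  tissues <- unique(psi_truth$tissue)
  sample_map <- data.frame(
    sample_id = paste0(rep(tissues, each = samples_per_tissue), "_s",
                       rep(seq_len(samples_per_tissue), length(tissues))),
    tissue = rep(tissues, each = samples_per_tissue),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(psi_truth)), function(r) {
    d <- if ("depth" %in% names(psi_truth)) psi_truth$depth[r] else depth
    sm <- sample_map[sample_map$tissue == psi_truth$tissue[r], , drop = FALSE]
    exc <- stats::rbinom(nrow(sm), d, 1 - psi_truth$psi[r] / 100)
    data.frame(event_id = psi_truth$event_id[r], sample_id = sm$sample_id,
               inc_up = d - exc, inc_down = d - exc, exc = exc,
               stringsAsFactors = FALSE)
  })
  list(counts = do.call(rbind, rows), sample_map = sample_map)
}

#' Simulate a protein half-life table with a planted P-rich effect
#'
#' Half-lives are log-normal. A subset of genes forms the skipped candidate
#' set, partitioned into the three proline-delta groups with fixed planted
#' P_fl/P_fs values; only the P-rich group's half-lives are scaled by
#' `effect`. Defaults reproduce the group sizes of the mouse 3T3 analysis
#' (36 / 76 / 80 skipped candidates against 3573 measured proteins) and a
#' median half-life of about 46 h.
#'
#' @param n_all Number of measured proteins (default 3573).
#' @param n_groups Sizes of the P-decreased / P-unchanged / P-rich groups
#'   (default `c(36, 76, 80)`).
#' @param effect Multiplier applied to P-rich half-lives (default 0.7; 1 =
#'   no effect).
#' @param meanlog,sdlog Log-normal parameters (defaults `log(46)`, 0.8).
#' @param seed Integer seed.
#' @return List with `halflife` (gene_id, half_life_h) and `candidates`
#'   (gene_id, psi, P_fl, P_fs) ready for [join_halflife()].
#' @export
simulate_halflife <- function(n_all = 3573L, n_groups = c(36L, 76L, 80L),
                              effect = 0.7, meanlog = log(46), sdlog = 0.8,
                              seed = 0L) {
  stopifnot(effect > 0, sum(n_groups) <= n_all, length(n_groups) == 3L)
  set.seed(seed)
  gene_id <- sprintf("HL%04d", seq_len(n_all))
  hl <- stats::rlnorm(n_all, meanlog, sdlog)
  grp <- rep(c("P-decreased", "P-unchanged", "P-rich"), times = n_groups)
  idx <- seq_len(sum(n_groups))
  hl[idx[grp == "P-rich"]] <- hl[idx[grp == "P-rich"]] * effect
  pvals <- list(`P-decreased` = c(10, 4), `P-unchanged` = c(8, 8),
                `P-rich` = c(5, 15))
  cand <- data.frame(
    gene_id = gene_id[idx], psi = 50,
    P_fl = vapply(grp, function(g) pvals[[g]][1L], numeric(1)),
    P_fs = vapply(grp, function(g) pvals[[g]][2L], numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(cand) <- NULL
  list(halflife = data.frame(gene_id = gene_id, half_life_h = hl,
                             stringsAsFactors = FALSE),
       candidates = cand)
}

#' Write a toy study to disk
#'
#' Writes `genome.fa`, `annotation.gtf`, `truth.tsv` and (when present)
#' `psi_truth.tsv` under `dir`. GTF and TSV files embed the seed and
#' generator version in a header comment; regenerating with the same seed
#' reproduces byte-identical files.
#'
#' @param toy A `toy_study` from [generate_toy_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_toy_data <- function(toy, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# seed=%d generator=%s", toy$seed, .GENERATOR_VERSION)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  Biostrings::writeXStringSet(toy$genome, fa)
  writeLines(c(hdr, toy$gtf), gtf)
  tr <- file.path(dir, "truth.tsv")
  writeLines(hdr, tr)
  suppressWarnings(utils::write.table(toy$truth, tr, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  paths <- c(fa, gtf, tr)
  if (!is.null(toy$psi_truth)) {
    ps <- file.path(dir, "psi_truth.tsv")
    writeLines(hdr, ps)
    suppressWarnings(utils::write.table(toy$psi_truth, ps, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        append = TRUE))
    paths <- c(paths, ps)
  }
  invisible(paths)
}
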