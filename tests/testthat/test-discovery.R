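# Geometry classification, candidate construction, gain filters,
# deduplication, and the brute-force translation oracle.

test_that("translation stops at the first stop, reports run-off and X codons", {
  expect_identical(translate_to_stop("ATGTAA"),
                   list(aa = "M", stop_reached = TRUE, truncated = FALSE))
  expect_identical(translate_to_stop("ATGCCACCG"),
                   list(aa = "MPP", stop_reached = FALSE, truncated = FALSE))
  expect_identical(translate_to_stop("ATGCCTGAATAG")$aa, "MPE")
  expect_true(translate_to_stop("ATGCCTGAATAG")$stop_reached)
  # codon containing N -> X, never a stop
  expect_identical(translate_to_stop("ATGTNATAA")$aa, "MX")
  # truncated trailing codon ignored but reported
  r <- translate_to_stop("ATGCC")
  expect_identical(r$aa, "M")
  expect_true(r$truncated)
  # through-stop mode emits '*'
  expect_identical(translate_to_stop("ATGTAACCC", through_stop = TRUE)$aa, "M*P")
})

test_that("geometry classes follow stop position and exon frame", {
  fix <- make_toy_fixture(n_per_class = 3L, seed = 21L)
  events <- do.call(rbind, lapply(fix$tx, classify_geometry))
  events$planted <- fix$toy$truth$class[match(events$gene_id,
                                              fix$toy$truth$gene_id)]
  # penultimate skip with stop in last exon: frameshifting -> Ultimate
  expect_true(all(events$geometry_class[events$planted == "Ultimate" &
                                        events$exon_length %% 3L != 0L] %in%
                  c("Ultimate")))
  # frame-preserving penultimate exon length (multiple of 3) -> Penulti_fp
  pfp <- events[events$planted == "Penulti_fp", ]
  expect_true(all(pfp$geometry_class == "Penulti_fp"))
  expect_true(all(pfp$exon_length %% 3L == 0L))
  # stop codon inside the penultimate exon -> Penultimate regardless of frame
  expect_true(all(events$geometry_class[events$planted == "Penultimate"] ==
                  "Penultimate"))
  # internal exons classified by their own frame
  expect_true(all(events$geometry_class[events$planted == "Internal_fs" &
                                        events$exon_index_skipped == 2L] ==
                  "Internal_fs"))
  expect_true(all(events$geometry_class[events$planted == "Internal_fp" &
                                        events$exon_index_skipped == 2L] ==
                  "Internal_fp"))
  # only Ultimate/Penultimate events are eligible for candidate construction
  expect_true(all(events$geometry_class[events$eligible] %in%
                  c("Ultimate", "Penultimate")))
  # the frame law: Ultimate implies skipped length not divisible by three
  expect_true(all(events$exon_length[events$geometry_class == "Ultimate"] %% 3L != 0L))
})

test_that("two-exon transcripts yield no skip events", {
  t2 <- structure(list(
    transcript_id = "t2", gene_id = "g2", chrom = "c", strand = "+",
    biotype = "protein_coding", exons = data.frame(start = c(1L, 20L),
                                                   end = c(10L, 40L)),
    exon_lengths = c(10L, 21L), orf_start = 1L, orf_end = 9L,
    stop_codon_exon_index = 1L, stop_first_genomic = 7L,
    stop_last_genomic = 9L), class = "TranscriptModel")
  expect_identical(nrow(classify_geometry(t2)), 0L)
})

test_that("candidate construction recovers planted gains and rejects wrong classes", {
  fix <- make_toy_fixture(n_per_class = 4L, seed = 5L)
  res <- discover_candidates(fix$genome, fix$tx)
  truth <- fix$toy$truth
  pass_truth <- truth[truth$passes, ]
  expect_setequal(res$passing$gene_id, pass_truth$gene_id)
  m <- merge(res$passing, pass_truth, by = "gene_id")
  expect_equal(m$aa_gained.x, m$aa_gained.y)
  expect_equal(m$aa_beyond_stop.x, m$aa_beyond_stop.y)
  expect_identical(m$new_cterm_aa, m$new_cterm)
  expect_true(all(res$passing$new_stop_in_last_exon))
  # frameshifting penultimate skips that shorten the protein are relabelled
  shorts <- res$candidates[res$candidates$outcome == "short", ]
  expect_true(all(shorts$geometry_class == "Penulti_short"))
  expect_true(all(shorts$aa_beyond_stop == 0L))
  # feeding a frame-preserving event violates the precondition
  ev <- do.call(rbind, lapply(fix$tx, classify_geometry))
  fp <- ev[ev$geometry_class == "Penulti_fp", ][1L, ]
  expect_error(build_candidate(fp, fix$tx[[fp$transcript_id]], fix$genome),
               "Ultimate or Penultimate")
})

test_that("gain filters are inclusive at the 20/10 boundary and monotone", {
  cand <- data.frame(aa_gained = c(20L, 19L, 50L, 20L, 25L),
                     aa_beyond_stop = c(10L, 15L, 9L, 10L, 24L),
                     stop_reached = TRUE, new_stop_in_last_exon = TRUE)
  cand$stop_reached[4] <- FALSE  # no stop: never passes
  expect_identical(apply_filters(cand), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # monotone: raising a threshold never admits more candidates
  fix <- make_toy_fixture(n_per_class = 3L, seed = 9L)
  cands <- discover_candidates(fix$genome, fix$tx)$candidates
  base <- sum(apply_filters(cands))
  for (mg in c(21L, 30L, 60L)) {
    expect_lte(sum(apply_filters(cands, min_gained = mg)), base)
  }
  for (mb in c(11L, 20L, 40L)) {
    expect_lte(sum(apply_filters(cands, min_beyond = mb)), base)
  }
})

test_that("deduplication keys on the 5-coordinate tuple and is idempotent", {
  row <- data.frame(
    transcript_id = "tB", gene_id = "g", chrom = "c", strand = "+",
    exon_index_skipped = 2L, geometry_class = "Ultimate",
    upstream_exon_end = 100L, exon_start = 200L, exon_end = 300L,
    downstream_exon_start = 400L, annotated_stop_position = 450L,
    divergence_point = 5L, new_cterm_aa = "AAA", aa_gained = 3L,
    aa_beyond_stop = 1L, new_stop_in_last_exon = TRUE, stop_reached = TRUE,
    outcome = "extended", contains_X = FALSE, stringsAsFactors = FALSE)
  iso <- row; iso$transcript_id <- "tA"         # same tuple, smaller id
  other_stop <- row; other_stop$transcript_id <- "tC"
  other_stop$annotated_stop_position <- 460L    # differs in element (5)
  dd <- deduplicate(rbind(row, iso, other_stop))
  expect_identical(nrow(dd), 2L)
  expect_true("tA" %in% dd$transcript_id)       # lexicographic representative
  expect_false("tB" %in% dd$transcript_id)
  expect_identical(deduplicate(dd), dd)         # idempotent
  # isoform duplicates from the generator collapse to one event per gene
  fix <- make_toy_fixture(n_per_class = 2L, seed = 13L)
  res <- discover_candidates(fix$genome, fix$tx)
  pre <- res$candidates[apply_filters(res$candidates), ]
  expect_identical(nrow(pre), 2L * nrow(res$passing))
  expect_true(all(grepl("\\.t1$", res$passing$transcript_id)))
})

test_that("alternative C-termini equal an independent brute-force translation (randomized genes)", {
  n <- 300L
  toy <- generate_candidate_genes(n, seed = 42L)
  dir <- withr::local_tempdir()
  write_toy_data(toy, dir)
  genome <- load_genome(file.path(dir, "genome.fa"))
  tx <- suppressMessages(load_annotation(file.path(dir, "annotation.gtf"),
                                         genome))
  expect_length(tx, n)
  gtfdf <- oracle_read_gtf(file.path(dir, "annotation.gtf"))
  chroms <- as.character(genome)
  res <- discover_candidates(genome, tx, min_gained = 0L, min_beyond = 0L)
  cands <- res$candidates
  expect_identical(nrow(cands), n)
  for (r in seq_len(nrow(cands))) {
    expect_identical(cands$new_cterm_aa[r],
                     oracle_candidate(gtfdf, chroms, cands$transcript_id[r]),
                     info = cands$transcript_id[r])
  }
  # and the planted truth is recovered exactly
  m <- merge(cands, toy$truth, by = "transcript_id")
  expect_equal(m$aa_gained.x, m$aa_gained.y)
  expect_equal(m$aa_beyond_stop.x, m$aa_beyond_stop.y)
})
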