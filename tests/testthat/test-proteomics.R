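# Frameshift search database, tryptic digestion, proteotypic flags and IP-MS
# enrichment calls.

test_that("database records are canonical prefix + new C-terminus", {
  canonical <- c(t1 = "MAAAKGGGR", t2 = "MPPPK")
  cands <- data.frame(transcript_id = "t1", exon_index_skipped = 2L,
                      divergence_point = 6L, new_cterm_aa = "WWWW")
  db <- build_fs_database(canonical, cands)
  expect_identical(nrow(db), 3L)
  fs <- db[db$origin == "predicted_frameshift", ]
  expect_identical(fs$sequence, "MAAAKWWWW")  # prefix of 5 + new C-terminus
  expect_identical(fs$fs_from, 6L)
  expect_identical(fs$accession, "t1_fs2")
  # unknown accession errors; identical fs sequence collapses
  bad <- transform(cands, transcript_id = "zz")
  expect_error(build_fs_database(canonical, bad), "unknown canonical")
  dup <- rbind(cands, cands)
  dup$exon_index_skipped[2] <- 3L
  expect_message(db2 <- build_fs_database(canonical, dup), "collapsed 1")
  expect_identical(sum(db2$origin == "predicted_frameshift"), 1L)
})

test_that("tryptic digestion cleaves after K/R except before P and enumerates missed cleavages", {
  d0 <- tryptic_digest("AAAKBBBR", max_missed = 0L, min_len = 4L)
  expect_setequal(d0$peptide, c("AAAK", "BBBR"))
  d1 <- tryptic_digest("AAAKBBBR", max_missed = 1L, min_len = 4L)
  expect_setequal(d1$peptide, c("AAAK", "BBBR", "AAAKBBBR"))
  # KP suppresses the cleavage
  expect_identical(tryptic_digest("AAKPGGR", max_missed = 0L, min_len = 1L)$peptide,
                   "AAKPGGR")
  # no K/R at all: the whole chain
  expect_identical(tryptic_digest("AAAQWN", max_missed = 2L, min_len = 1L)$peptide,
                   "AAAQWN")
  # length filter
  expect_identical(nrow(tryptic_digest("AKAKAK", max_missed = 0L, min_len = 6L)), 0L)
})

test_that("digestion reconstruction and missed-cleavage composition laws hold", {
  set.seed(5)
  aas <- c("A", "G", "K", "R", "P", "L", "S", "T", "W", "E")
  for (i in 1:200) {
    s <- paste(sample(aas, sample(5:60, 1), replace = TRUE), collapse = "")
    d0 <- tryptic_digest(s, max_missed = 0L, min_len = 1L)
    expect_identical(paste(d0$peptide, collapse = ""), s)
    d2 <- tryptic_digest(s, max_missed = 2L, min_len = 1L)
    for (m in 1:2) {
      dm <- d2[d2$missed_cleavages == m, , drop = FALSE]
      for (r in seq_len(nrow(dm))) {
        # a k-missed peptide is the concatenation of k+1 consecutive 0-missed ones
        parts <- d0$peptide[d0$start >= dm$start[r] & d0$end <= dm$end[r]]
        expect_length(parts, m + 1L)
        expect_identical(paste(parts, collapse = ""), dm$peptide[r])
      }
    }
  }
})

test_that("proteotypic flags match a brute-force substring search over a toy database", {
  set.seed(9)
  canonical <- vapply(1:30, function(i) paste(
    sample(c("A", "G", "L", "S", "K", "R", "E", "D", "V", "T"), 40,
           replace = TRUE), collapse = ""), character(1))
  names(canonical) <- sprintf("P%02d", 1:30)
  cands <- data.frame(
    transcript_id = names(canonical)[1:8], exon_index_skipped = 2L,
    divergence_point = 21L,
    new_cterm_aa = c("WWWWKWWWYK", "WWWWKWWWYK", "YYYYKRFFFF", "HHHHKHHHH",
                     "MMMMKMMMM", "CCCCKCCCC", "NNNNKNNNN", "QQQQKQQQQ"))
  db <- suppressMessages(build_fs_database(canonical, cands))
  peps <- flag_proteotypic(db, max_missed = 2L, min_len = 6L)
  # oracle: substring containment over all database entries
  for (r in seq_len(nrow(peps))) {
    parents <- db$accession[vapply(db$sequence, function(s)
      grepl(peps$peptide[r], s, fixed = TRUE), logical(1))]
    expect_setequal(strsplit(peps$parents[r], ";")[[1]], parents)
    expect_identical(peps$proteotypic[r], length(parents) == 1L)
  }
  s <- attr(peps, "summary")
  expect_true(s[["proteotypic_fs_peptides"]] <= s[["fs_mapping_peptides"]])
  # every reported peptide touches the novel segment
  expect_true(all(peps$end >= db$fs_from[match(peps$source_accession,
                                               db$accession)]))
})

test_that("peptide m/z uses monoisotopic masses with fixed cys modification", {
  # PEPTIDER: monoisotopic [M+2H]2+
  m <- peptide_mz("PEPTIDER", charge = 2L)
  expect_equal(m, (97.05276 + 129.04259 + 97.05276 + 101.04768 + 113.08406 +
                   115.02694 + 129.04259 + 156.10111 + 18.010565 +
                   2 * 1.007276) / 2, tolerance = 1e-6)
  expect_equal(peptide_mz("C", carbamidomethyl = TRUE) -
               peptide_mz("C", carbamidomethyl = FALSE), 57.02146 / 2,
               tolerance = 1e-6)
  expect_error(peptide_mz("AB*"), "non-standard")
})

test_that("IP enrichment normalizes by the median and requires all replicates above threshold", {
  ratios <- data.frame(
    protein = c("A", "B", "Tubulin beta", "D", "E", "F"),
    r1 = c(2.4, 1.1, 5.0, 1.0, 0.9, 1.0),
    r2 = c(3.0, 1.0, 5.0, NA, 0.9, 1.0))
  r <- call_ip_enrichment(ratios, threshold = 1.5)
  # median normalization makes each replicate column's median exactly 1
  expect_equal(median(r$r1), 1)
  expect_equal(median(r$r2, na.rm = TRUE), 1)
  expect_true(r$enriched[r$protein == "A"])          # both replicates > 1.5
  expect_identical(r$reason[r$protein == "Tubulin beta"], "excluded_family")
  expect_false(r$enriched[r$protein == "Tubulin beta"])
  expect_identical(r$reason[r$protein == "D"], "not_quantified")
  expect_false(r$enriched[r$protein == "E"])
  expect_error(call_ip_enrichment(ratios[, 1:2]), "replicate")
})
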