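# Amino-acid composition, PxxP-family motif scanning/scoring, proline
# grouping, coil fraction and top-delta selection.

test_that("composition excludes stop/X symbols and sums to one", {
  expect_equal(aa_composition("PPPP")[["P"]], 1)
  pa <- aa_composition("PA")
  expect_equal(pa[["P"]], 0.5)
  expect_equal(pa[["A"]], 0.5)
  expect_equal(aa_composition("MPPE*P")[["P"]], 3 / 5)  # stop excluded
  expect_equal(sum(aa_composition("MKRPLLWWXX*")), 1)
  expect_error(aa_composition("**XX"), "countable")
  expect_equal(proline_content("PAPA"), 50)
})

test_that("3'UTR composition averages three translate-through-stop frames", {
  # plus-strand single-gene toy: poly-A UTR -> lysine in every frame
  fa <- withr::local_tempfile(fileext = ".fa")
  chrom <- paste0("CCC", "ATGGCCGCC", "TAA", strrep("A", 320))
  writeLines(c(">c1", chrom), fa)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  at <- 'gene_id "g"; transcript_id "t"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";'
  writeLines(c(
    sprintf("c1\tx\texon\t1\t%d\t.\t+\t.\t%s", nchar(chrom), at),
    sprintf("c1\tx\tCDS\t4\t12\t.\t+\t.\t%s", at),
    sprintf("c1\tx\tstop_codon\t13\t15\t.\t+\t.\t%s", at)), gtf)
  genome <- load_genome(fa)
  t1 <- load_annotation(gtf, genome)[["t"]]
  comp <- utr_composition(t1, genome)
  expect_equal(comp$utr[["K"]], 1)
  expect_equal(unname(comp$frames[, "K"]), c(1, 1, 1))
  # brute-force oracle on a random 60-nt UTR: average of three hand frames
  set.seed(2)
  utr <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  chrom2 <- paste0("CCC", "ATGGCCGCC", "TAA", utr)
  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", chrom2), fa2)
  gtf2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    sprintf("c1\tx\texon\t1\t%d\t.\t+\t.\t%s", nchar(chrom2), at),
    sprintf("c1\tx\tCDS\t4\t12\t.\t+\t.\t%s", at),
    sprintf("c1\tx\tstop_codon\t13\t15\t.\t+\t.\t%s", at)), gtf2)
  genome2 <- load_genome(fa2)
  t2 <- load_annotation(gtf2, genome2)[["t"]]
  comp2 <- utr_composition(t2, genome2)
  frame_profile <- function(off) {
    sub <- substring(utr, 1 + off)
    n <- nchar(sub) - nchar(sub) %% 3
    aa <- seqinr::translate(seqinr::s2c(substr(sub, 1, n)))
    aa <- aa[aa != "*"]
    table(factor(aa, levels = names(comp2$utr))) / length(aa)
  }
  manual <- (frame_profile(0) + frame_profile(1) + frame_profile(2)) / 3
  expect_equal(unname(comp2$utr), as.numeric(manual), tolerance = 1e-12)
  expect_equal(sum(comp2$cds), 1)
})

test_that("motif scanning counts overlapping matches and agrees with a regex oracle", {
  motifs <- builtin_motifs()
  expect_identical(scan_motif("PAAP", motifs$PxxP), 1L)
  expect_identical(scan_motif("PAAPAAP", motifs$PxxP), 2L)  # overlap allowed
  expect_identical(scan_motif("AAAA", motifs$PxxP), 0L)
  expect_identical(scan_motif("RPPPKR", motifs$RxxPxxP), 0L)
  expect_identical(scan_motif("KAVPALP", motifs$classI), 1L)
  set.seed(7)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:250) {
    s <- paste(sample(aas, sample(5:60, 1), replace = TRUE,
                      prob = ifelse(aas %in% c("P", "R", "K"), 3, 1)),
               collapse = "")
    for (mn in names(motifs)) {
      expect_identical(scan_motif(s, motifs[[mn]]),
                       oracle_scan(s, motifs[[mn]]), info = paste(mn, s))
    }
  }
})

test_that("frequency scores reproduce the observed/expected rules exactly", {
  motifs <- builtin_motifs()
  uniform <- setNames(rep(0.05, 20), c("A", "R", "N", "D", "C", "Q", "E",
                                       "G", "H", "I", "L", "K", "M", "F",
                                       "P", "S", "T", "W", "Y", "V"))
  # worked example: PxxP on a 43-residue sequence with one match
  seq43 <- paste0("PAAP", strrep("G", 39))
  stopifnot(nchar(seq43) == 43)
  r <- motif_frequency_score(seq43, motifs$PxxP, uniform)
  expect_identical(r$observed, 1L)
  expect_equal(r$expected, 0.0025 * 40)
  expect_equal(r$score, 10)
  # no match -> 0; observed == expected -> 1
  expect_equal(motif_frequency_score(strrep("G", 43), motifs$PxxP,
                                     uniform)$score, 0)
  s2 <- paste0("PAAP", strrep("G", 396))  # L=400, expected = 0.0025*397
  r2 <- motif_frequency_score(s2, motifs$PxxP, uniform)
  expect_equal(r2$score, 1 / (0.0025 * 397 / 1))
  bg0 <- uniform; bg0[["P"]] <- 0; bg0 <- bg0 / sum(bg0)
  expect_error(motif_frequency_score("PAAP", motifs$PxxP, bg0),
               "inconsistent background")
  expect_error(motif_frequency_score("PAAP", motifs$PxxP, uniform * 2),
               "sum to 1")
  # simulation: sequences drawn from the background give mean score near 1
  set.seed(11)
  bg <- background_frequencies()
  scores <- replicate(400, {
    s <- paste(sample(names(bg), 60, replace = TRUE, prob = bg), collapse = "")
    motif_frequency_score(s, motifs$PxxP, bg)$score
  })
  p_match_none <- mean(scores == 0)
  expect_equal(mean(scores), 1, tolerance = 0.15)
  expect_true(p_match_none > 0 && p_match_none < 1)
})

test_that("proline grouping uses the +/-3 point bands with boundaries in the middle class", {
  expect_identical(proline_group(10, 5), "P-decreased")
  expect_identical(proline_group(10, 10), "P-unchanged")
  expect_identical(proline_group(5, 15), "P-rich")
  expect_identical(proline_group(13, 10), "P-unchanged")  # boundary +3
  expect_identical(proline_group(10, 13), "P-unchanged")  # boundary -3
  expect_identical(proline_group(c(10, 5), c(5, 15)),
                   c("P-decreased", "P-rich"))
})

test_that("coil fraction counts C labels over the full length", {
  expect_equal(coil_fraction("CCCC"), 1)
  expect_equal(coil_fraction("HHEE"), 0)
  expect_equal(coil_fraction("CHCE"), 0.5)
  expect_error(coil_fraction(""), "empty")
  expect_error(coil_fraction("CHQ"), "labels")
})

test_that("top proline-delta selection orders by gain, breaks ties by id, prepends upstream context", {
  cands <- data.frame(
    id = c("b", "a", "c", "d"),
    fl_cterm = c("AAAAA", "AAAAA", "AAAAA", "PAAAA"),
    fs_cterm = c("PAAAA", "PPAAA", "PAAAA", "AAAAP"),
    upstream = c("MKLVWXYZQRS", "GG", NA, "HHHHHHHHHHHH"))
  top1 <- select_top_proline_delta(cands, n = 1L)
  expect_identical(top1$id, "a")                       # +40 beats +20
  top3 <- select_top_proline_delta(cands, n = 3L)
  expect_identical(top3$id, c("a", "b", "c"))          # tie b/c -> id order
  expect_identical(top3$fs_seq[2], "KLVWXYZQRSPAAAA")  # last 10 upstream
  expect_identical(top3$fs_seq[1], "GGPPAAA")          # short upstream as-is
  expect_message(select_top_proline_delta(cands, n = 10L), "available")
})

test_that("planted P-rich frameshift C-termini show proline and PxxP enrichment over canonical", {
  fix <- make_toy_fixture(n_per_class = 5L, seed = 23L)
  res <- discover_candidates(fix$genome, fix$tx)
  ult <- res$passing[res$passing$geometry_class == "Ultimate", ]
  fl <- vapply(ult$transcript_id, function(tid) {
    t <- fix$tx[[tid]]
    translate_to_stop(spliced_sequence(t, fix$genome), t$orf_start)$aa
  }, character(1))
  P_fs <- vapply(ult$new_cterm_aa, proline_content, numeric(1))
  P_fl <- vapply(substring(fl, nchar(fl) - 19L), proline_content, numeric(1))
  expect_gt(mean(P_fs), mean(P_fl))   # planted at ~30% vs background ~5%
  pxxp <- builtin_motifs()$PxxP
  obs_fs <- vapply(ult$new_cterm_aa, scan_motif, integer(1), motif = pxxp)
  obs_fl <- vapply(substring(fl, nchar(fl) - 19L), scan_motif, integer(1),
                   motif = pxxp)
  expect_gt(mean(obs_fs), mean(obs_fl))
})
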