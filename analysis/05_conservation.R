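#!/usr/bin/env Rscript
# Step 5 — cross-species frame structure.
#
# Scans the last exon of every passing candidate in all three forward frames
# (annotated frame relabelled 0) and highlights frames with more than 50
# residues before the first stop, then runs the hypergeometric overlap test
# on a mock two-species candidate split of the toy gene set.

library(utr3frame)

genome <- load_genome("results/toy/genome.fa")
tx <- load_annotation("results/toy/annotation.gtf", genome)
passing <- read.delim("results/discovery_candidates.tsv")

rows <- lapply(passing$transcript_id, function(tid) {
  t <- tx[[tid]]
  n <- nrow(t$exons)
  exon_seq <- spliced_sequence(t, genome)
  last_start <- sum(t$exon_lengths[-n]) + 1L
  last <- substring(exon_seq, last_start)
  # offset of the annotated frame within the last exon
  off <- (last_start - t$orf_start) %% 3L
  off <- (3L - off) %% 3L
  sc <- scan_last_exon(last, annotated_offset = off, min_len = 50L)
  data.frame(transcript_id = tid, frame_m1 = sc$lengths[["-1"]],
             frame_0 = sc$lengths[["0"]], frame_p1 = sc$lengths[["+1"]],
             highlighted = paste(sc$highlighted, collapse = ","))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/frame_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("three-frame last-exon ORF lengths (AA):\n")
print(tab)

# mock conservation: split candidate loci into two overlapping "species" sets
set.seed(0)
loci <- passing$gene_id
ortho <- data.frame(species_a = loci, species_b = paste0("h_", loci))
set_a <- sample(loci, 4L)
set_b <- paste0("h_", sample(loci, 4L))
ov <- overlap_from_sets(ortho, set_a, set_b, universe = length(loci))
cat(sprintf("overlap test: N=%d K=%d n=%d k=%d p=%.3g\n",
            ov$N, ov$K, ov$n, ov$k, ov$p_value))
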