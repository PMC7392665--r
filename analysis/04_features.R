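#!/usr/bin/env Rscript
# Step 4 — sequence features of the alternative C-termini.
#
# Compares amino-acid composition of canonical (fl) vs frameshift (fs)
# C-termini, scores the SH3-binding proline-rich motif families
# (observed/expected frequency scores), assigns proline-delta stability
# groups, and selects the top proline-gain candidates for disorder analysis.

library(utr3frame)

genome <- load_genome("results/toy/genome.fa")
tx <- load_annotation("results/toy/annotation.gtf", genome)
passing <- read.delim("results/discovery_candidates.tsv")

fl_protein <- vapply(passing$transcript_id, function(tid) {
  t <- tx[[tid]]
  translate_to_stop(spliced_sequence(t, genome), t$orf_start)$aa
}, character(1))
fl_cterm <- substring(fl_protein, pmax(1L, nchar(fl_protein) - 19L))

P_fl <- vapply(fl_cterm, proline_content, numeric(1))
P_fs <- vapply(passing$new_cterm_aa, proline_content, numeric(1))
groups <- proline_group(P_fl, P_fs)
cat("proline content: fl mean", round(mean(P_fl), 1), "% vs fs mean",
    round(mean(P_fs), 1), "%\n")
cat("proline-delta groups:\n"); print(table(groups))

motif_tab <- rbind(
  cbind(set = "fl", score_motifs(setNames(fl_cterm, passing$transcript_id))),
  cbind(set = "fs", score_motifs(setNames(passing$new_cterm_aa,
                                          passing$transcript_id))))
write.table(motif_tab, "results/motif_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
agg <- aggregate(score ~ set + motif, motif_tab, mean)
cat("mean motif frequency scores (fl vs fs):\n")
print(reshape(agg, idvar = "motif", timevar = "set", direction = "wide"))

feat <- data.frame(id = passing$transcript_id, fl_cterm = fl_cterm,
                   fs_cterm = passing$new_cterm_aa,
                   upstream = substring(fl_protein, 1L,
                                        pmax(0L, nchar(fl_protein) - 20L)),
                   P_fl = P_fl, P_fs = P_fs, group = groups)
write.table(feat, "results/cterm_features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

top <- select_top_proline_delta(feat, n = min(200L, nrow(feat)))
write.table(top, "results/top_proline_delta.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("selected %d candidates with the largest proline gain (max +%.1f%%)\n",
            nrow(top), max(top$delta_P)))
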