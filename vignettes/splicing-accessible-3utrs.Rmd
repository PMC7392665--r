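---
title: "Methods: discovering and characterizing splicing-accessible coding 3'UTRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and characterizing splicing-accessible coding 3'UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utr3frame)
```

## The model

Nonsense-mediated decay (NMD) degrades transcripts whose stop codon lies
upstream of the last exon-exon junction. Skipping the *penultimate* exon is
the exception: if the annotated stop codon sits in the penultimate exon the
skip removes it, and if it sits in the last exon a frameshifting skip moves
it out of frame — either way translation continues into the annotated 3'UTR
and terminates at a new stop codon in the last exon, which NMD does not
flag. The protein keeps its entire N-terminal sequence up to the skipped
exon and acquires a 3'UTR-encoded C-terminus.

The pipeline formalizes this as pure frame arithmetic over a transcript
model (exons ordered 5'→3' in transcript orientation, ORF boundaries in
transcript coordinates):

* every internal exon of a ≥ 3-exon protein-coding transcript yields one
  skip event, classified by stop-codon location and exon length mod 3;
* for the two extension-capable classes (`Ultimate`, `Penultimate`) the
  skipped mRNA is translated from the annotated start codon;
* the divergence point is the first amino acid differing from the
  canonical protein — computed at the protein level, because the hybrid
  junction codon can re-encode the same residue;
* `aa_gained` counts residues from the divergence point to the new stop,
  and `aa_beyond_stop` the subset whose first codon base lies strictly 3'
  of the annotated stop codon's last base *in genomic coordinates*, which
  is robust to codons spanning the splice junction;
* a candidate passes with `aa_gained >= 20`, `aa_beyond_stop >= 10`
  (inclusive boundaries), a reachable stop, and that stop in the last exon
  (the NMD-escape gate).

`Penulti_short` deserves a note: by exon geometry alone it is
indistinguishable from `Ultimate` (stop in last exon, penultimate exon
length not divisible by three). What distinguishes it is the *translated
outcome* — the new frame terminates upstream of the annotated stop,
producing a shorter protein. `classify_geometry()` therefore labels such
events `Ultimate`, and `build_candidate()` relabels them when translation
shows `aa_beyond_stop == 0` with a shorter product. Candidates whose new
frame reaches no stop at all are flagged `non_stop` and never pass.

Deduplication collapses transcript isoforms describing the same splicing
event: the key is the 5-tuple (upstream-exon end, skipped-exon start and
end, downstream-exon start, annotated stop position) on one chromosome,
and the representative is the lexicographically smallest transcript id — a
deterministic tie-break so repeated runs agree.

## PSI estimation

Upstream inference tools model read generation; here PSI is estimated
directly from junction counts with the standard ratio estimator,

$$\mathrm{PSI} = 100\cdot\frac{(i_u+i_d)/2}{(i_u+i_d)/2 + e},$$

halving inclusion reads because an included exon contributes two junctions
while an excluded one contributes one. Events need ≥ 20 supporting reads
(`inc_up + inc_down + exc`) to count as expressed; "supporting reads" is
deliberately the sum of all reads informative about the event. Per-tissue
PSI averages *expressed* samples only; an event is alternatively spliced
when some tissue PSI is strictly below 90. The companion simulator draws
`exc ~ Binomial(depth, 1 - PSI/100)` and gives each of the `depth - exc`
inclusion molecules one read on *each* inclusion junction, which makes the
estimator exactly calibrated (`(depth - exc)/depth` is an unbiased binomial
proportion); the tests verify a mean within 3 standard errors of a planted
PSI of 70 at depth 10^4.

Tissue similarity uses 1 minus the weighted Pearson correlation with each
event's PSI median absolute deviation as weight, so variable exons drive
the structure; weights are normalized internally, making the MAD scale
constant irrelevant. Events with any empty tissue cell are dropped from
the distance computation rather than pairwise-deleted — the simplest rule
with deterministic output. Differentiation-stage inputs can be reduced to
motif-discovery sets: background = PSI > 90 or < 20 in *every* stage,
target = PSI range > 50 between any two stages; the sets are disjoint by
construction.

## Sequence features

Composition is defined over the 20 standard residues; stop symbols from
translate-through-stop frames and `X` from N-containing codons are excluded
from numerator and denominator. 3'UTR coding potential is profiled by
translating the first 100 residues of all three frames after the stop
codon, reading *through* internal stops, and averaging the three frame
profiles; the paired CDS profile uses the last 100 residues of the
annotated protein.

Motif occurrences are counted at every start offset, so overlapping
matches each count (documented because it affects only multi-match
sequences). The frequency score of a motif in a sequence of length $L$ is
$\mathrm{obs}/\mathrm{exp}$ with
$\mathrm{exp} = (L - m + 1)\prod_j p_j$, where $p_j$ sums the background
frequencies of the residue class at motif position $j$ (wildcard = 1); a
sequence with no match scores 0. The per-sequence reading of "expected for
a sequence of that length" is the only one under which per-sequence scores
are well defined. The hydrophobic class Φ in the class I/II SH3 motifs is
configurable with default {A,V,I,L,M,F,W,Y,P}, a common SH3-ligand
convention. The default background is the SwissProt release-average
composition; a proteome FASTA can supply an organism-specific table.

Proline-delta groups use the ±3 percentage-point bands; the strict
inequalities leave the boundary values unassigned, and they are placed in
the middle (`P-unchanged`) class as the conservative bin. Disorder
analysis selects the 200 candidates with the largest proline *gain*
(configurable; 200 follows the operative protocol where two stated values
disagreed) and prepends up to 10 upstream residues when available; %coil
is simply the fraction of `C` labels in an externally predicted
secondary-structure string.

## Conservation and proteomics

Last-exon ORFs are scanned in all three forward frames with no ATG
requirement — the frames continue an upstream CDS — measuring residues to
the first stop; frames are relabelled so the annotated frame is 0, and
frames strictly longer than 50 residues are highlighted. Ortholog overlap
uses the upper-tail hypergeometric probability; because the original
universe behind the published overlap is not stated, the default universe
here is the union of 1:1-orthologous candidate loci and is explicitly
configurable — the published p-value is therefore not a target this
package tries to reproduce.

The search database appends, per deduplicated candidate, the canonical
prefix up to the divergence point plus the new C-terminus. Digestion is
Mascot-style trypsin: cleave C-terminal to K/R except before P, up to 2
missed cleavages, minimum peptide length 6 (the engine defaults the
original search relied on; both surfaced as parameters). A peptide "maps
to" a frameshift C-terminus only if it includes at least one residue of
the novel segment; it is proteotypic when its sequence occurs in exactly
one database entry (plain substring containment, checked against a
brute-force all-pairs search in the tests). IP-MS enrichment divides each
replicate column by its median and requires a normalized ratio above 1.5
in every replicate; tubulin and heat-shock families are excluded as
standard pulldown false positives.

Half-life group comparisons default to Welch's t test on log-transformed
half-lives: the distributions are strongly right-skewed and the group
variances differ, so the unequal-variance variant on the log scale is the
defensible default even though the classic equal-variance form is offered;
a Wilcoxon p-value is reported alongside, and a Benjamini–Hochberg column
is added across the group tests (the primary report stays unadjusted, with
the adjustment available for readers who want it).

## What the synthetic data emulates — and what it does not

`generate_toy_genome()` constructs genes *backwards from amino-acid
truths*: the new-frame content of the last exon is an explicit residue
string reverse-translated with a codon table in which no codon ends in T.
Because every stop codon starts with T, the out-of-frame (canonical)
reading of such codon runs can never terminate — except where a single
T-ending codon is planted deliberately, creating the canonical stop at an
exact offset. This yields exact control of `aa_gained` and
`aa_beyond_stop` on both strands, fail-filter controls at 19/10 and 25/9,
isoform duplicates differing only in 5'UTR extent, and decoy transcripts
(non-coding; stop-less) that the loader must drop. Toy chromosomes stay
in the tens of kilobases so the full suite runs in seconds; the randomized
property generator (1000 genes) and the 100-seed half-life simulations are
the largest problem sizes used.

Planted study conditions follow the analysis the package implements: 5
genes per geometry class; per-tissue PSI of 95 (constitutive) or 40 in one
tissue (skipped); junction depth 200 with 3 samples per tissue; half-life
tables of 3573 proteins with skipped-candidate groups of 36/76/80 and a
multiplicative P-rich effect of 0.7 on log-normal half-lives
(median ≈ 46 h, log-sd 0.8, a realistic ~10-fold spread).

The generator does **not** emulate: read-level sequencing (no FASTQ, no
alignment errors), overdispersed junction counts, batch effects between
library protocols, incomplete or erroneous annotations beyond the two
decoy types, paralogy (every planted gene is unique, so proteotypic
fractions run high), or correlated tissue structure. Passing tests
demonstrate the *arithmetic* of the pipeline is right against planted
truth — not that real annotations are clean, nor that real junction counts
are binomial.

## Numerical and degenerate-input choices

* Coordinates are GTF-style 1-based inclusive throughout; all strand
  handling is confined to the transcript-model layer, so downstream frame
  arithmetic is orientation-free.
* Codons containing non-ACGT bases translate to `X` and never match a
  stop; candidates whose C-terminus contains `X` carry a flag.
* Transcripts with a CDS+stop length not divisible by three, a
  non-canonical stop, or a non-contiguous ORF are dropped with per-reason
  counts rather than failing the run — real annotations contain such
  records. Annotated selenocysteine readthrough or incomplete-CDS tags
  fall into these drop classes and are counted, not silently kept.
* A stop codon split across a junction belongs to the exon containing its
  first base (a deterministic ownership rule).
* Two-exon transcripts produce an empty event list, not an error.
* Weighted correlation requires a positive weighted variance in each
  column and a positive total weight; both degenerate cases raise errors
  naming the cause.
* `mad()` is used with its default scale constant; it cancels in the
  normalized weights.

## Limitations

The discovery stage models single-exon skips only; alternative 3'/5'
splice sites and multi-exon skips, which can expose the same frames, are
reachable only through the frame scanner. The NMD model is the
last-exon-stop geometry gate, not the 50-nt junction rule. PSI is a
point estimate without posterior uncertainty, and the expression filter
interacts with depth (shallow samples are simply excluded). The
hypergeometric universe is a modelling choice that materially changes
p-values and must be justified per dataset. Published candidate counts
from pinned genome releases and public RNA-seq accessions require those
exact inputs and are out of desk-scale scope here; this package
establishes correctness of the machinery on planted truth instead.
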