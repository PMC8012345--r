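---
title: "Models and methods behind vatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vatkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vatkit)
```

vatkit analyses clusters of NLR resistance-gene homologs whose LRR2 domain is
a tandem array of near-identical 65-aa (195-nt) repeat units, and ships a
ground-truthed simulator of such clusters. This vignette explains the models,
the tunable parameters, the numerical choices, and what the simulation-based
checks do and do not establish about real data.

## The simulated gene and cluster

`make_ancestor()` builds a five-exon, four-intron gene. Exon 2 carries `k`
identical tandem copies of one random 195-nt unit; exon lengths are fixed at
999 / (249 + 195·k + 249) / 999 / 600 / 528 nt with 400-nt GT…AG introns, so
that the spliced CDS is a complete open reading frame encoding 1467 aa at
k = 4 (65 aa more or less per unit). Binding sites for four synthetic primer
pairs are embedded at fixed offsets; the sites are 20-mers over {A, C, G}
only, so a planted site can never spell a stop codon on either strand, and
the codons overlapping a site are immutable during evolution ("primers
unmutated"). The resulting amplicon arithmetic is closed-form:

| pair class             | location                              | product (nt)            |
|------------------------|---------------------------------------|--------------------------|
| `repeat_spanning`      | introns on each side of exon 2        | 598 + 195·k             |
| `exon2_internal`       | inside exon 2, flanking the array     | 272 + 195·k (467 at k=1)|
| `exon1_exon2`          | end of exon 1 → downstream of array   | 1307 + 195·k (1502 at k=1; +2345 with the intron-1 insertion) |
| `reverse_strand_exon1` | exon 1 of the reverse retro-copy      | 933, k-independent      |

The repeat-spanning flank constant (598 = 50 nt in each flanking intron plus
the two 249-nt non-repeat parts of exon 2) is not dictated by the biology and
is exposed through `amplicon_constants`; the 467 / 1502 / 3847 / 933 values
are the assay's landmark product sizes and are fixed by the geometry.

`evolve_cluster()` runs a continuous-time event process over gene lineages
for `tree_height` time units:

* **duplication** (rate `duplication_rate`/lineage) copies a whole locus;
  lineages carry their full event logs, so duplicates share prefix history.
  The locus count is capped at 10 per accession, comfortably above the
  observed range.
* **unequal crossover** (rate `crossover_rate`) adds or removes one repeat
  copy (±1 unit, equal probability), bounded to k ∈ [1, 7] — the observed
  range of repeat counts; out-of-range proposals are dropped. A single unit
  has no tandem partner to mispair with, so k = 1 is an absorbing state —
  which keeps single-repeat homologs (including the reverse retro-copy) a
  stable class, as they are in the cluster this emulates.
* **TE insertion** (rate `te_insertion_rate`) inserts either a 2345-nt
  element into intron 1 (the class that shifts the exon1–exon2 product from
  1502 to 3847 nt) or a 2540-nt LINE-1-like element into intron 2; the locus
  becomes `pseudo_insertion`.
* **stop gain** (rate `stop_gain_rate`) plants a TAA at a random internal
  codon (`pseudo_stop`).
* **substitution** (rate `sub_rate` per site) proposes a random base change.
  Proposals that would create a stop codon, or fall in a protected primer
  codon, are rejected. Synonymous and non-coding proposals are always
  accepted; nonsynonymous proposals are accepted with probability
  `nonsyn_accept` (default 0.2), multiplied by `nonsyn_hot_factor` (default
  4) when the codon lies in `nonsyn_hot_window` (codons 25–35 of a repeat
  unit). This acceptance-thinning scheme reproduces the "hills and valleys"
  structure of nonsynonymous density without modelling per-site selection
  coefficients.
* at most one **retro-copy** event (probability `retro_prob` per history)
  pastes a single-repeat copy of an intact lineage onto the reverse strand,
  with the reverse-pair primer sites planted in its exon 1.

The defaults (`duplication_rate = 1.4`, `tree_height = 1`) make the expected
number of lineages per accession e^1.4 ≈ 4, matching a panel that averages
about four homologs per accession with a wide spread; `crossover_rate = 1`
spreads k over 1–7 with the ancestor at k = 4; `sub_rate = 0.01` gives
percent-scale divergence between homologs; `retro_prob = 0.5` makes the
reverse-strand homolog common but not universal. None of these rates is
measured in nature; they are free parameters chosen once to land in the
regime the assay addresses.

`simulate_panel()` evolves each accession independently from the shared
ancestor. Intergenic spacers are drawn once per panel from the config seed
and reused, so the null process (all rates zero) yields byte-identical
regions across accessions. Truth tables record, per locus, the region
coordinates, strand, class, repeat count and CDS; the per-accession "digit
string" is the sorted multiset of repeat counts over all loci with an intact
repeat array (pseudogenes keep their arrays and amplify, so they carry a
digit too — only the band-pattern flags distinguish them).

What the simulator does **not** emulate: intron sequence realism beyond GT/AG
boundaries, recombination between accessions, indels outside whole-unit
gain/loss, TE sequence structure, and any genome context beyond the cluster
region. Checks that pass on these simulations therefore validate the
*computational chain* (coordinates, arithmetic, decoding, statistics), not
field performance on real genomic idiosyncrasies.

## Homology scanning and classification

`scan_region()` seeds exact 12-mers, clusters them into candidate windows
(gap ≤ 250 nt), and refines each window by local pairwise alignment (match
+1, mismatch −1, gap open −4, extend −1, via Biostrings). Identity is
computed over aligned columns; coverage is relative to the query. When at
most 30 query nt were left unaligned at an end, the hit is extended to the
full query extent, so a terminal mismatch does not erode exon boundaries.
Thresholds default to identity ≥ 40 and query coverage ≥ 30 — deliberately
permissive, mirroring homology-search practice for diverged gene families;
the coverage reading (query, not target) is a documented interpretation
choice.

`assemble_models()` chains same-strand hits with gaps ≤ `max_intron`
(3000 nt) and collinear exon order (a repeated or out-of-order exon opens a
new locus, so tandem copies separated by short spacers are not merged);
junctions snap to the nearest GT/AG (AC/CT on the minus strand) within
±30 nt. `classify_locus()` then applies, in order: `partial` (a required exon
query is unmatched), `pseudo_insertion` (an inter-exon gap exceeds
`insert_threshold` = 2000 nt — plain introns here are 400 nt, TE-bearing ones
2745–2940 nt, so 2000 separates the two cleanly while staying under the
grouping threshold), `pseudo_stop` (internal stop in the spliced frame), else
`intact`.

Two numerical details matter. First, homology-derived exon edges can sit a
few nt off the true splice grid, so a greedy frame repair considers trimming
0–2 nt from each exon edge (gene order) and keeps the variant minimising
in-frame stop codons — off-frame sequence is stop-rich (roughly one stop per
20 codons), which makes the in-frame variant essentially always the unique
minimiser, while a genuine premature stop (exactly one in-frame stop)
survives repair and is still called. Second, a codon spanning an exon–exon
junction is chimeric under boundary drift, so stops confined to junction
codons are ignored by the ORF test.

## Repeat annotation and virtual CDSs

`find_repeats()` is unsupervised: a period scan over lags 195 ± 9 finds the
self-similar region (windowed self-match fraction, window = one unit; below
`min_selfmatch` = 0.6 the CDS is declared repeat-free, k = 0); a small-window
run-walk localises the array start; the codon-aligned anchor maximising the
identity of the first block to the consensus of the following blocks fixes
the phase (ties resolve leftmost); copies are then grown in both directions
while their identity to the running consensus stays ≥ `min_copy_identity`
(70% — the units are "near-perfect", and the threshold is exposed). Copy
boundaries are constrained to codon boundaries so that excision keeps the
virtual CDS in frame; partial terminal copies are left in the flanks.

Two intrinsic limits are worth noting. A single isolated copy has no tandem
partner and is invisible to period analysis — precisely why single-repeat
homologs need dedicated primer pairs at the bench; `find_repeats()` accepts a
`reference_unit` to annotate k = 1, and `annotate_repeat_set()` automates
this for a set of homologous CDSs (first pass unsupervised, consensus from
the pooled copies, second pass reference-guided). Second, a few flanking
nucleotides can match the unit tail by chance, so the phase of a single noisy
CDS carries codon-scale ambiguity; the set-level second pass pins the phase,
which matters when units are pooled into one alignment.

`build_virtual_cds()` excises every copy and records a strictly increasing
virtual→original coordinate map; original length = virtual length + excised
length holds exactly on every input. `partition_blocks()` returns the
pre-LRR2 / LRR2 / post-LRR2 intervals (the array is the LRR2 block).

## Band decoding

`find_binding_sites()` requires ≤ `max_mismatch` (default 1) mismatches and
an exact 3'-terminal base; `predict_amplicons()` pairs forward sites with
downstream reverse sites within the maximum product length, in both template
orientations. `infer_accession()` decodes a band set: each distinct
repeat-spanning band of length L yields one digit `round((L − f)/195)`
(tolerance ±5 nt; digits outside 1–7 or lengths off the lattice raise
errors); an exon-2-internal product at the k = 1 length marks a single-repeat
homolog and appends digit 1 unless already implied; a reverse-strand product
(933 nt) flags a reverse homolog (also appending a digit 1 if absent); an
exon1–exon2 product on the insertion-shifted lattice (+2345 nt) sets
`has_insertion_pseudo` without adding a digit. A plain-lattice reading is
accepted only for k in 1–7; this matters because the +2345 shift happens to
sit within the band tolerance of twelve extra repeat units, and the bounded-k
rule resolves the ambiguity in favour of the insertion class. Because bands
of co-migrating homologs merge, the decoded homolog count is a minimum —
duplicated k values collapse, which is the documented behaviour of the
underlying gel assay.

## Per-site nonsynonymous probability

For codon site *i*, over all unordered sequence pairs with gap-free,
stop-free codons, `n_diff(i)` counts pairs with different codons and
`n_ns(i)` those encoding different amino acids; `p(i) = n_ns/n_diff` is the
conditional probability that a codon change is an amino-acid change,
undefined where no pair differs. The pairwise definition (rather than
change-versus-consensus or tree-aware counting) is symmetric and estimable
per site without a phylogeny; that is an interpretation choice, made once
and flagged here.

`smooth_curve()` applies Nadaraya–Watson smoothing with a Gaussian kernel on
the nucleotide axis (site positions at codon midpoints; undefined sites carry
zero weight). Bandwidths follow the scale appropriate to each block: 20 nt by
default for the flanking blocks (anything in the 20–25 bp range behaves
similarly) and
8 nt for the repeat block; both are plain arguments.

`permutation_envelope()` permutes the per-site `(n_diff, n_ns)` tuples
uniformly across the block's codon sites — preserving the marginal
distribution of change intensity while destroying positional structure —
recomputes the smoothed curve B times (default 1000) and takes pointwise
empirical α/2 and 1−α/2 quantiles (type-7). Peaks/valleys are positions where
the observed curve leaves the band. The permuted unit (whole site tuples) is
a design choice; permuting within-site counts would break the n_ns ≤ n_diff
coupling. On alignments with iid columns the mean flagged fraction sits near
α, which the acceptance run verifies (mean exceedance within [α/2, 2α] over
100 simulations at B = 500).

## Distances, trees, breakpoints

`tn93_distance()` implements the Tamura–Nei (1993) closed form with base
frequencies estimated from the pair and the two transition classes (A↔G,
C↔T) separated from transversions; saturated pairs (non-positive logarithm
argument) return Inf with a warning. `nj_tree()` is canonical Saitou–Nei
agglomeration with lowest-index tie-breaking; a negative branch length is
clamped to zero and its deficit moved to the sister edge, and the final
trifurcation is solved by the three-point equations. On any additive matrix
the topology and patristic distances are recovered exactly (ape's
implementations serve as independent cross-checks in the tests, never as the
implementation). `bootstrap_support()` resamples whole codons when the
alignment length is a multiple of 3 and scores each internal split of the
point tree by the percentage of replicate trees containing it (500
replicates by default); saturated replicate distances are capped at twice
the largest finite entry. Multiple alignment (`progressive_align()`) is
delegated to MAFFT's default progressive strategy — residues are never
edited, only gaps introduced.

`breakpoint_scan()` is a deliberately simplified stand-in for
genetic-algorithm recombination detection: for every candidate codon boundary
with at least one variable site on each side, NJ trees are fitted to the two
segments' p-distances and the improvement of the two-tree fit over the single
whole-alignment tree is scored by least-squares distance residuals, each
segment's residual weighted by its length (a p-distance over a segment of
length L has sampling variance ∝ 1/L, so weighting keeps the noise
contribution flat across candidate positions while genuine incongruence
grows with the span it covers — unweighted residuals let short noisy
segments dominate). Significance comes from a codon-column permutation null:
p = (1 + #{permutation best ≥ observed})/(n_perm + 1). p-distances (not
TN93) are used inside the scan because they remain finite and fast on short
segments under permutation; user-facing trees still use TN93. The scan finds
one breakpoint, not a multi-breakpoint model average, and its p-value is
calibrated against positional shuffling, not a coalescent null — both
simplifications are intentional scope limits.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and restores the caller's
RNG state. The packaged checks use: a 500-accession panel for the
simulate→PCR→decode round trip; 500 simulated CDSs per mutation level for
repeat recovery (2–7 copies; 5% per-copy mutation as the reference level,
with 10% and 15% recorded as a degradation curve); 100 random additive
matrices (≤12 taxa) for NJ; 100 iid-column alignments (10 × 100 codons,
B = 500) for band calibration; 100 two-topology concatenations (6 taxa,
600 + 600 nt) and 100 single-topology nulls (n_perm = 59, candidate stride 6)
for breakpoint power and size; and 8-accession panels with a 5-fold hot
window for peak detection. These sizes give stable rates while keeping a full
run in the tens of minutes on one CPU; they are stated here so that larger
re-runs are a one-line change.

## Known limitations

* The simulator's independence of accessions ignores shared population
  history; digit-spectrum comparisons across accessions are therefore
  optimistic about independence.
* Unsupervised repeat detection requires k ≥ 2 and ~≥ 70% copy identity;
  heavily diverged or single-copy arrays need the reference-guided mode.
* The homology scanner assumes point divergence between query and target
  exons; large internal indels within an exon would split hits.
* The breakpoint scan assumes one dominant breakpoint and equal-rate
  segments; mosaic alignments with several junctions dilute its score.
* In-silico PCR ignores thermodynamics (Tm, dimers, competition); a band is
  predicted wherever the mismatch and length rules allow one.
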