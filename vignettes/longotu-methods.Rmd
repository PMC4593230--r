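---
title: "OTU inference from long amplicon reads: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OTU inference from long amplicon reads: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longotu)
```

## The problem

Operational taxonomic units (OTUs) are the working currency of amplicon
microbiome profiling: 16S rRNA gene reads are clustered at a fixed sequence
dissimilarity (typically 1–6 %), and each cluster is treated as a proxy for
a taxon. Two things make this hard for long circular-consensus (CCS) reads.
First, the dominant residual error mode of CCS data is the single-base
insertion or deletion; a naive distance treats each of these as a
difference and inflates OTU counts. Second, greedy heuristic clusterers are
input-order dependent and tend to produce clusters wider than the nominal
threshold. `longotu` addresses both with an exact pipeline: all-versus-all
global alignment, an indel-aware genetic distance, and complete-linkage
hierarchical clustering, plus the simulation machinery needed to benchmark
the whole procedure against a known ground truth.

## Genetic distance between two reads

Each pair of sequences is aligned globally (Needleman–Wunsch with affine
gaps, Gotoh's algorithm; implemented in C++). Scoring defaults are the
EMBOSS needle conventions — match +5, mismatch −4, gap open 10, gap extend
0.5, a gap run of length $L$ costing $\mathrm{open} + L\cdot\mathrm{ext}$ —
and all four are configurable. Ties among co-optimal traceback paths are
resolved with the fixed priority diagonal > gap-in-second > gap-in-first,
so alignments are reproducible across platforms and input orders; pairs are
additionally aligned in canonical id order so the distance matrix does not
depend on how the input file was sorted.

The alignment is then post-processed:

1. terminal gap columns (in either row) are removed — with amplicons of
   unequal span they represent missing sequence, not differences;
2. every internal gap run of length exactly one is deleted from both rows —
   this is the CCS-specific step that discounts the dominant error mode;
   runs of length ≥ 2 are kept.

The distance is the number of differences over the number of examined
columns, where each surviving gap run counts once ("an indel is one
event"), and — by default — its columns also collapse to a single column in
the denominator, so a $k$-base indel weighs exactly as much as one
substitution. The alternative denominator (full run length) is available
via `collapse_runs = FALSE`; the two conventions differ only in the third
decimal for realistic amplicon data, but the collapsed form is the one
consistent with counting an indel once in both numerator and denominator.
Columns containing `N` in either row are excluded from both counts, and the
`N` spacer of merged short-read pairs is excised (its interval is recorded
at merge time) before any alignment.

A banded variant of the aligner (`band` argument) restricts the dynamic
program to a corridor around the length-difference diagonal. For reads of
one amplicon the optimal path drifts from that diagonal only by the
cumulative indel imbalance — tens of bases at 1 % error — so a band of 50
reproduces the full search exactly (asserted empirically in the tests)
at a fraction of the cost. The default remains the full matrix; the
benchmark harness passes `band = 50` explicitly.

## Clustering

Clustering is ordinary agglomerative hierarchical clustering of the
dissimilarity matrix via `stats::hclust`, with complete linkage as the
default: cutting a complete-linkage tree at height $h$ guarantees every
cluster has diameter ≤ $h$, which is precisely the "OTU at $h$
dissimilarity" contract. Average and single linkage are available for
comparison. Leaves are sorted by id before clustering, so the tree is
independent of input order; cuts (`cut_tree`) are inclusive at the
threshold, i.e. "3 % similarity" keeps merges at dissimilarity ≤ 0.03.
OTUs are labeled `OTU_1, OTU_2, …` by decreasing size (ties by smallest
member id), and tables carry raw counts, per-sample normalized abundances,
and a per-sample centered/scaled variant for heat-map display. The
supporting operations mirror standard practice: a minimum-support filter
(default ≥ 10 reads per OTU, inclusive), singleton counts, representative
selection by minimum mean intra-OTU distance (ties to the smallest id),
and a small-versus-large OTU quality diagnostic (mean per-read quality,
Kolmogorov–Smirnov and Welch tests) that flags error-driven OTUs.

The pass-binning experiment — binning CCS reads by pass count
(3–8, 9–14, 15–23, ≥ 24), sampling 1000 reads per bin and clustering each
bin separately at 3 % — is a composition of `shuffle_records`,
subsetting, `distance_matrix` and `cut_tree`; no bespoke operation is
needed and none is provided.

## The synthetic benchmark

The generator emulates the structure of a curated 16S database without any
download. A random root sequence (1500 bp) is evolved into genus ancestors
by independent per-site substitution (probability 0.10), and each ancestor
into genome sequences (probability 0.03). Under this model two genomes of
one genus differ at a fraction $2q(1-q) + \tfrac{2}{3}q^2 \approx 5.9\,\%$
of sites for $q = 0.03$, and genomes of different genera at roughly 19 % —
so the 1–6 % clustering window sits between read-error noise and
genome-level signal, which is the regime the method targets. Mock
communities sample 100/250/500 genomes (low/medium/high complexity)
without replacement, 10 replicates per level.

Amplicons are cut from fixed coordinates of the (ungapped) synthetic
reference — V4 (389–801) for 2 × 150 merged pairs, V3–V4 (227–801) for
2 × 250 and 450 bp CCS, V1–V4 (4–801) for 750 bp CCS, V1–V6 (4–1506,
clamped to the sequence length) for 1450 bp CCS — or by IUPAC primer
matching for arbitrary input.

Read simulation follows two error models:

* **CCS** — per-read accuracy drawn from Normal(0.99, 0.01), truncated (not
  resampled) at 1 and floored at a nominal minimum; the number of errors is
  Binomial(length, 1 − accuracy), split mismatch : insertion : deletion =
  6 : 21 : 73 and placed uniformly. Qualities encode the drawn accuracy; a
  synthetic monotone accuracy→passes map (15 passes at accuracy 0.99,
  ± 6 passes per percentage point) annotates `passes` purely so that
  pass-binning recipes are exercisable — it is not a model of real
  polymerase kinetics.
* **Short paired** — substitutions only, at a rate rising linearly from
  0.1 % at the first cycle to 1 % at the last, a simple monotone stand-in
  for the learned quality profiles of short-read simulators. The pair is
  merged exactly as experimental pairs are: reverse-complement the second
  read and join with an `N` spacer (10 nt in simulation; the experimental
  convention trims 42 bp and inserts a 42 bp spacer).

Reads are down-sampled to exactly 20 per genome and shuffled before
clustering. The full printed configuration therefore emits
10 × 100 × 20 × 5 = 100,000 reads at low complexity and 500,000 at high;
`run_benchmark` reproduces these totals exactly and can stream FASTQ plus
a truth table to disk.

What the generator deliberately does **not** model: chimeras, abundance
skew (every genome contributes equally), context-dependent error hotspots,
length heterogeneity of real 16S genes, and real hypervariable-region
structure (divergence is uniform along the sequence). Consequently a
passing benchmark shows that the pipeline recovers a known partition under
the stated error structure — not that it resolves real taxa; in real data
the advantage of long reads is, if anything, larger, because divergent
sites cluster in regions short reads never see.

## Evaluation

Clustering quality uses the Hubert–Arabie adjusted Rand index, computed
from the contingency table; the degenerate case (expected index equal to
the maximum index, e.g. two all-singleton partitions) returns 0 by the
usual convention. The implementation is cross-checked in the tests against
a brute-force pair-counting oracle and against `mclust::adjustedRandIndex`.
Precision (cluster purity) and recall (class cohesion) are size-weighted so
both equal 1 exactly on a perfect clustering. `threshold_sweep` evaluates
cuts at 1–6 % and reports the best-ARI row per run; medians across
replicates use the mean-of-middle-two convention. The ARI-versus-read-length
trend is exposed as an ordinary least-squares fit with ANOVA — routine
statistics, reported not re-derived.

The scaled-down directional comparison (`benchmark_directional`) runs 3
mock communities of 25 genomes with 10 reads per genome and two
technologies (merged 2 × 150 and 1450 bp CCS), chosen so the complete
all-versus-all alignment stage finishes in a few minutes on one CPU while
still containing ~24,000 genome pairs' worth of decisions per replicate;
the headline expectation is that the median best-threshold ARI of the long
reads is at least that of the short reads.

## Entropy profiling

Per-column Shannon entropy $H_i = -\sum_a f_{ai}\log_2 f_{ai}$ is computed
over the four plain bases only; gaps and ambiguity codes are excluded and
the frequencies renormalized, keeping $H \le 2$ bits (treating the gap as a
fifth symbol would break that ceiling and conflate coverage with
diversity). Columns with no plain base get $H = 0$ and a low-coverage flag.
The alignment is first projected onto a reference row (columns where the
reference has a gap — insertions relative to it — are dropped), the
reference row itself is excluded from the frequencies, and entropies are
averaged in non-overlapping 10 bp windows, dropping a trailing partial
window so every window averages the same number of positions. Peaks of the
profile localize hypervariable regions; the test suite verifies exact
colocalization on constructed alignments with known variable blocks.

## Mixed-technology refinement

`hybrid_analysis` implements the joint-clustering workflow: CCS reads are
trimmed to the short-read region (coordinates or primer pair; reads
missing the region are dropped and counted), short reads are sub-sampled
(seeded) to the CCS count, and the pooled set is clustered at each
threshold. OTUs with ≥ 10 reads are classified shared (≥ 1 read from each
technology) or technology-specific. For the shared OTUs richest in CCS
reads, the full-length CCS members are re-clustered at the same threshold;
the resulting cluster count is the sub-OTU count — substructure that only
the long reads resolve. Strand orientation for arbitrary input uses
both-strand alignment identity against an anchor panel sampled from the
input itself (default 10 sequences), replacing an external database search
with the same contract.

## Numerical and interface choices

* Phred offset fixed at 33; qualities decoding above 93 are rejected
  (offset-64 files are out of scope).
* The ± 100 bp size filter uses inclusive bounds, the permissive reading.
* The CCS quality rule is strict (`> Q30` over 90 %), the merged-read rule
  inclusive (`≥ Q30` over 97 %, spacer excluded) — both exposed through
  one `strict` flag.
* Barcode demultiplexing is 5'-anchored exact matching (zero mismatches);
  primers are stripped with IUPAC degeneracy when present.
* All stochastic steps take explicit seeds; a fixed seed reproduces
  byte-identical outputs, and `distance_matrix` results are invariant to
  the `jobs` parameter and to input order.
* Problem sizes used by the shipped checks: the alignment oracle runs on
  200 random pairs ≤ 10 bp against an independent full-matrix DP; the
  clustering oracle on 50 random matrices (n ≤ 12) against a naive
  $O(n^3)$ agglomerator; the directional benchmark on 3 × 25 genomes as
  above. These sizes are the package's own choice of a desk-scale
  experiment with stable statistics.

## Known limitations

Pairwise alignment cost grows quadratically with read count; no k-mer
prefilter is implemented, so inputs beyond a few tens of thousands of
reads are impractical. The distance matrix is held in memory (8 bytes per
pair — about 100 MB at 5000 reads), which is comfortable at the scale the
package targets; an out-of-core triangular store would be the next step
for larger cohorts. Chimera detection is only a hook (an external score
table plus threshold), taxonomy assignment and covariance-model alignment
are out of scope, and the MSA-based distance consumes an externally
produced alignment. The accuracy→passes annotation is synthetic, and the
generator's uniform-divergence model understates the positional structure
of real 16S variation.

## A 60-second example

```{r example, eval = FALSE}
db    <- synth_reference_db(n_genera = 10, genomes_per_genus = 5, seed = 1)
mock  <- build_mocks(db, "low", n_replicates = 1, seed = 1,
                     n_genomes = 10)[[1]]
sim   <- sim_community_reads(mock, "ccs_1450", reads_per_genome = 5,
                             seed = 1)
reads <- shuffle_records(sim$reads, seed = 2)
D     <- distance_matrix(reads, band = 50)
part  <- cut_tree(linkage(D, "complete"), h = 0.03)
truth <- setNames(sim$truth$genome_id, sim$truth$read_id)
adjusted_rand_index(part, truth)
```
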