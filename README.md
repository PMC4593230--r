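# longotu

OTU inference for long-read 16S rRNA amplicon data by exact pairwise
alignment and hierarchical clustering.

## The problem

Microbiome studies cluster 16S rRNA gene amplicon reads into operational
taxonomic units (OTUs) at a fixed sequence dissimilarity (1–6 %) and use
the clusters as taxon proxies. Long circular-consensus (CCS) reads cover
far more of the gene than short reads, but their residual errors are
dominated by single-base insertions and deletions, which naive distances
count as differences and thereby inflate OTU numbers; greedy heuristic
clusterers add input-order dependence and clusters wider than the nominal
threshold. `longotu` is for researchers who want exact, reproducible OTU
calls from CCS (or mixed CCS + short-read) amplicon data at the scale
where all-versus-all comparison is feasible (up to tens of thousands of
reads).

## The method

For every pair of reads `longotu` computes a Needleman–Wunsch global
alignment under affine gap scoring (match +5, mismatch −4, gap open 10,
gap extend 0.5; Gotoh's algorithm in C++ with a deterministic traceback),
then post-processes the alignment by

1. removing terminal gap columns, and
2. deleting every internal gap run of length exactly one — the CCS error
   mode — from both rows.

The genetic distance is

```
d = (mismatches + surviving gap runs) / examined columns
```

with each surviving gap run counted once and collapsed to one column in
the denominator (a k-base indel weighs like one substitution), and `N`
columns excluded. The dissimilarity matrix is clustered with
complete-linkage hierarchical clustering (`stats::hclust`); cutting the
tree at height *h* yields OTUs whose maximum intra-cluster distance is
guaranteed ≤ *h*. Supporting machinery covers read preprocessing (pair
merging with an `N` spacer, quality-fraction / length filters, exact
barcode demultiplexing), a mock-community read simulator (CCS accuracy ~
Normal(0.99, 0.01), error ratio mismatch:insertion:deletion = 6:21:73;
position-dependent substitution profile for short pairs), adjusted Rand
index evaluation, Shannon-entropy profiling of hypervariable regions, and
a mixed-technology sub-OTU refinement workflow.

## Worked example

Simulate one small mock community, cluster its full-length CCS reads, and
compare against the genome of origin:

```r
library(longotu)

db    <- synth_reference_db(n_genera = 10, genomes_per_genus = 5, seed = 1)
mock  <- build_mocks(db, "low", n_replicates = 1, seed = 1,
                     n_genomes = 10)[[1]]
sim   <- sim_community_reads(mock, "ccs_1450", reads_per_genome = 5,
                             seed = 1)
reads <- shuffle_records(sim$reads, seed = 2)

D     <- distance_matrix(reads, band = 50)
part  <- cut_tree(linkage(D, "complete"), h = 0.03)
truth <- setNames(sim$truth$genome_id, sim$truth$read_id)

length(unique(part))               # 10
adjusted_rand_index(part, truth)   # 1
threshold_sweep(D, truth)
```

which prints

```
    h n_otus n_singletons       ari precision recall
 0.01     14            4 0.9060403         1   0.92
 0.02     11            1 0.9778180         1   0.98
 0.03     10            0 1.0000000         1   1.00
 0.04     10            0 1.0000000         1   1.00
 0.05     10            0 1.0000000         1   1.00
 0.06     10            0 1.0000000         1   1.00
```

At 1 % dissimilarity residual read errors still split four reads off as
singletons; from 3 % on, the 50 reads collapse exactly onto the 10 source
genomes (ARI = 1), and the complete-linkage guarantee keeps every OTU's
diameter within the threshold.

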