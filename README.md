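# tissueGRN

Tissue-specific gene regulatory network (GRN) inference and evaluation in R.

Multicellular organisms reuse largely the same transcription factors (TFs)
across tissues, yet regulate very different target sets in each. Given
gene-level RNA-Seq count matrices from many libraries per tissue and a list
of TF genes, this package reconstructs a directed, weighted TF→target
network per tissue, evaluates the ranked predictions against ChIP-derived
target sets, and characterizes the networks (hub TFs, cross-tissue edge
sharing, scale-free topology, density modules). It is aimed at systems
biologists who have counts and a TF list and want tissue-resolved regulatory
hypotheses with honest, null-calibrated quality metrics.

## The method

For every target gene *j*, its standardized expression profile is regressed
on the candidate TFs' profiles with an ensemble of regression trees grown on
bootstrap samples (a random subset of K = ⌊√p⌋ TFs considered per split).
The weight of the edge TF*i* → gene*j* is

&nbsp;&nbsp;&nbsp;&nbsp;*w*<sub>ij</sub> = (1/*n*) · mean over trees of the
total variance reduction attributed to splits on TF*i*,

and all TF→target pairs are ranked globally by *w* (ties broken
lexicographically, so rankings are platform-stable and nested under
truncation). Mutual-information comparators (CLR and MRNET, on plug-in MI
with equal-frequency binning) are included for benchmarking.

Ranked networks are evaluated against a positive target set — either a gene
list or ChIP peak summits assigned to genes within 10 kb of the gene span —
by AUROC (Mann–Whitney, ties ½) and AUPR (step-wise precision–recall
integration), against a 10,000-permutation label null, and by one-tail
Fisher enrichment (exact hypergeometric tail). Network characterization
includes degree centrality at a fixed edge cutoff, cross-tissue coefficient
of variation of degree (sample-sd convention), key-TF calls (degree > 2000
at the top-1M scale), directed cross-tissue edge overlap, log-log power-law
fits of the out-degree spectrum, and Markov clustering (MCL, inflation 2.5)
for module detection.

A first-class synthetic-data module (`sim_config`, `simulate_dataset`,
`simulate_chip_truth`) plants a ground-truth multi-tissue network with
power-law out-degrees, generates negative-binomial counts from a
steady-state latent model, and emits ChIP-like peaks with controllable
false-negative/false-positive rates — so every stage of the pipeline is
testable with no external data.

## Worked example

```r
library(tissueGRN)

# a small two-tissue world with a known network
cfg <- sim_config(n_tf = 20, n_genes = 120, n_samples_per_tissue = 80,
                  n_tissues = 2, avg_targets_per_tf = 5, seed = 42)
ds <- simulate_dataset(cfg)

# normalize and call expressed genes per tissue
factors <- tmm_factors(ds$counts)
cpm  <- to_cpm(ds$counts, factors)
lcpm <- to_cpm(ds$counts, factors, log_transform = TRUE)
sets <- expressed_sets(cpm, ds$tissue_of)

# infer the tissue-1 network from its libraries
libs1 <- names(ds$tissue_of)[ds$tissue_of == "tissue1"]
grn <- infer_grn(lcpm[sets$tissue1, libs1], ds$network$tf_ids,
                 n_trees = 100, seed = 1, tissue = "tissue1")
grn
#> Ranked edge list: 2380 edges, 20 regulators, 120 targets [tissue1]
#>   regulator target    weight
#> 1    TF0019 G00118 0.3817157
#> 2    TF0008 TF0010 0.3805500
#> ...

# how well does the ranking recover the planted network?
evaluate_network(grn, ds$tissue_networks$tissue1, n_perm = 1000, seed = 2)
#> AUROC 0.8907  AUPR 0.4889  (36 positives / 2380 universe)
#> random baseline (1000 permutations): AUROC 0.5000  AUPR 0.0185

# ChIP-style evaluation of the hub TF (noisy simulated peaks, 10 kb rule)
ann  <- toy_annotation(ds$network$gene_ids)
chip <- simulate_chip_truth(ds$tissue_networks$tissue1, "TF0004",
                            fnr = 0.2, fpr = 0.01, annotation = ann, seed = 3)
truth <- positive_target_set("TF0004", assign_peak_targets(chip$peaks, ann),
                             sets$tissue1)
evaluate_ranking(grn, truth)
#> AUROC 0.7790  AUPR 0.4225  (11 positives / 120 universe)

# modules in the thresholded network
mcl_cluster(top_edges(grn, 300))
#> MCL partition: 119 nodes in 16 modules (inflation 2.50)
#> module sizes: 17 13 12 10 10 9 9 8 7 5 ...
```

Reading the numbers: the full ranking separates true from false edges with
AUROC 0.89 where a random network scores 0.50, and the hub TF's top-ranked
targets recover its (deliberately corrupted) ChIP positives at AUROC 0.78.
The edge count 2380 is the complete candidate space, 20 × 120 − 20 self-pairs;
use `top_edges` to threshold before downstream analyses.

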