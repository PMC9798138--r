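# phosbench

Data-driven inference of kinase–substrate signalling networks from global
phosphoproteomics promises context-specific wiring diagrams that do not
depend on biased pathway annotations — but does it work? `phosbench` is an
R package for answering that question quantitatively. It benchmarks six
pairwise association measures at recovering kinase–substrate (KS) and
substrate–substrate (SS, shared-kinase) networks from phosphosite ×
sample abundance matrices, against gold standards built from
phosphosite-resolved interactome databases, with and without a
phosphopeptide sequence-similarity filter.

It is aimed at computational biologists who want to (i) stress-test
association-based network inference on simulated signalling dynamics
before trusting it on real data, and (ii) run the full evaluation
framework — gold-label construction, regulation filters, similarity
thresholds, AUROC/precision–recall/Fisher metrics and permutation nulls —
on their own phosphoproteome matrices.

## What is implemented

**Association measures.** For phosphosite profiles $x, y$ of length $k$:
Pearson, Spearman (Pearson on midranks) and Kendall correlation (tau-b),
plug-in mutual information
$\mathrm{MI}(x,y) = \sum_{i,j} p_{ij} \log \frac{p_{ij}}{p_i p_j}$
on optimally discretized profiles (exact 1-D k-means by dynamic
programming), the directional functional chi-squared statistic
normalized as $(\chi^2_f - \mathrm{df}) / \sqrt{2\,\mathrm{df}}$, and a
Gaussian graphical model: partial correlations
$\rho_{ik} = -\,\Omega_{ik} / \sqrt{\Omega_{ii}\,\Omega_{kk}}$ from the
inverse $\Omega$ of the Schäfer–Strimmer shrinkage correlation matrix.
Every measure also scores time-lagged candidate pairs
($t = 1,\dots,n-1$ against $t = 2,\dots,n$) as directed associations.

**Simulation study.** A linear-Gaussian simulator on the consensus Raf
pathway (11 nodes, 19 edges), $X_i \sim N(\sum_k \omega_{ik} X_k,
\sigma^2)$ with $|\omega_{ik}| \sim U[0.5, 2]$ and random sign, sampled
either as independent structural draws per timepoint (default) or as a
stabilized VAR(1); length and intermittent-sampling sweeps score network
recovery by AUROC.

**Evaluation.** Gold label matrices in $\{1, 0, \mathrm{NA}\}$ honouring
kinase residue-class specificity (S/T vs Y), optional augmentation with
machine-learning predictions above a strict probability cutoff, a ≥5
true-positive gate, AUROC (rank-sum with midranks),
$\log_{10}(\mathrm{AUPRC}/\mathrm{baseline})$, top-20% Fisher enrichment,
a 10,000-shuffle permutation p-value, and a kinase-prioritisation rank
test.

**Sequence-similarity filter.** 15-mer phosphopeptide windows, BLOSUM62
Smith–Waterman local alignment normalized by the geometric mean of
self-alignment scores, dataset-specific thresholds at the median of
sampled same-kinase (TP) pair similarities, score zeroing below the
threshold, and a filter-only predictor.

**Synthetic phosphoproteomes.** A generator with known ground truth —
kinases with sequence motifs, motif-matched substrate windows,
activity-driven time-series and inhibitor-panel matrices, and the
matching gold interactome — so the entire pipeline is testable without
downloads.

## Worked example

Recover the Raf pathway from one simulated dataset, then run the
similarity filter on a synthetic phosphoproteome:

```r
library(phosbench)

net <- sample_weights(load_raf_network(), seed = 1)
ds  <- simulate_dataset(net, k = 100, seed = 2)
gg  <- ggm_matrix(ds$values)
compute_metrics(gg, truth_labels(net))
#>   measure auroc auprc baseline log10_auprc_ratio top20_odds_ratio top20_fisher_p  n_tp  n_tn
#> 1 ggm     0.968 0.939    0.345             0.434             38.9      0.0000284    19    36

permutation_pvalue(gg, truth_labels(net), n_perm = 10000, seed = 3)
#> <perm_result> observed AUROC 0.9678, p = 0 (10000 permutations)
```

The GGM ranks 19 true edges against 36 non-edges with AUROC 0.968; its
precision–recall area is 0.939 against a 0.345 positive baseline
(log-ratio 0.43), true edges are 39-fold enriched in the top 20% of
predictions, and no score permutation beats the observed AUROC.

```r
w   <- generate_world(seed = 4)                       # 8 kinases x 10 substrates
tsd <- generate_timeseries(w, n_timepoints = 8, seed = 5)
thr <- compute_threshold(w$interactome, w$windows, character(0), seed = 6)
thr
#> <similarity_threshold> TP median 0.1819 (TN median 0.136; 360 TP / 2800 TN pairs)

pe <- pearson_matrix(tsd$values)
ss <- build_ss_labels(w$interactome, w$sites)
compute_metrics(pe, ss)$auroc                                   # 0.599
compute_metrics(apply_similarity_filter(pe, w$windows, thr), ss)$auroc  # 0.688
```

Same-kinase peptide pairs are modestly more similar than random pairs
(medians 0.182 vs 0.136); zeroing substrate–substrate associations below
the TP-median threshold lifts the Pearson SS AUROC from 0.60 to 0.69 on
this world — the filter's benefit, reproduced end-to-end on synthetic
data.

Full grids run through `run_sweep()` (simulation length/interval sweeps)
and `run_benchmark()` (datasets × measures × modes × filters × gold
variants, with skip log and manifest); results are tidy tibbles with
`autoplot()` methods.

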