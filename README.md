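# comap

Analysis of paired single-cell histone-modification (ChIC) and
full-length transcriptome data during early embryonic development.
The package is aimed at researchers studying how chromatin states and
transcription become coupled as cells commit to lineages: it takes sparse
cell x bin chromatin counts and spliced/unspliced RNA counts from the
same cells and asks where the repressive mark H3K27me3 spreads in cis,
when that spreading silences genes, which genes are later demethylated in
a cell-type-specific way, and which transcription factors activate or
repress the enhancers carrying their motifs.

## What it computes

* **ChIC LSA embedding** — cells x bins counts weighted by
  log term frequency and inverse document frequency
  (tf = 1 + log2 f, idf = log2(N/n_k)), pivoted unique normalization
  (each cell divided by (1−s)·pivot + s·nnz_i, slope s = 0.25),
  deterministic truncated SVD, removal of depth-correlated topics, and a
  kNN graph.
* **Metacells** — seeded k-means pooling of transcriptionally similar
  cells into pseudo-replicates, with per-mark balancing (equal numbers of
  H3K27me3 and H3K4me1 cells per metacell, minimum 20 of each) and
  modal-label / mean-latent-time annotation.
* **Domains** — a two-state negative-binomial HMM on pooled pseudo-bulk
  bins (posterior ≥ 0.4 filter), MACS-style local-enrichment subpeaks
  (score ≥ 50) that replace their parent domains, promoter / genic /
  gene-covering / intergenic classification, and a two-mark
  unique/co-enriched partition.
* **Cis-spreading** — per center bin (detected in ≥ 5% of pluripotent
  cells), OLS of the 100-kb flanking signal on the center signal across
  metacells, Y = β0 + β1·X, with a Pearson-correlation spreading flag and
  a lineage likelihood-ratio test (BH-adjusted).
* **Silencing** — per gene, OLS of log2 unspliced density (counts per kb
  intron) on log2 H3K27me3 density (counts per kb of domain) across
  metacells.
* **Coupling** — per metacell, the Pearson correlation between gene-body
  mark signal and expression across genes, tracked along latent time.
* **TF programs** — chromVAR-style bias-corrected motif deviation scores
  on H3K4me1-unique peaks, per-TF lasso models (70/30 split, 10-fold CV,
  one-SE lambda) predicting motif activity from TF expression, the TF's
  own gene-body chromatin, pseudotime and lineage; permutation p-values
  with BH selection (padj < 0.01); activator/repressor by the sign of the
  expression weight, regulated/independent by the self-chromatin weights.
* **Differential chromatin** — metacells as replicates, expression
  filter, TMM normalization, NB GLM likelihood-ratio tests with Cox-Reid
  trended/tagwise dispersions, and demethylated-gene selection at
  FDR < 0.05 and log2FC < −1.
* **Synthetic data** — a generator that plants all of the above
  (spreading loci, silenced genes, demethylated genes, TF programs) with
  known parameters, so every stage has a recovery test.

## Worked example

The numbered scripts under `analysis/` run the whole study: simulate the
default dataset (2,000 cells per histone mark, 5,000 five-kb bins, 800
genes), run the pipeline, and evaluate every stage against the planted
truth.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_run_pipeline.R
Rscript analysis/03_spreading_silencing.R
```

prints (seed 1):

```
Simulated 2000 cells per mark over 5000 bins and 800 genes (seed 1):
 planted 40 spreading centers (beta1 = 0.8), 60 silenced genes
 (slope = -1.0), 30 demethylated genes, 20 TFs (8 act / 8 rep / 4 null).
...
QC retained 1963 H3K27me3 and 1975 H3K4me1 cells (3938 total).
44 balanced metacells kept; mean latent time spans 0.04-0.84.
Called 893 H3K27me3 and 520 H3K4me1 domains/subpeaks.
...
Spreading: 40/40 planted centers recovered, mean beta1 0.801 (true 0.8),
 100% flagged; ...
Silencing: 60 planted genes fit, mean slope -1.052 (true -1), 100% negative.
Coupling: correlation of per-metacell r with latent time = 0.85
```

Reading these numbers: the spreading regression recovers the planted
slope β1 = 0.8 to within 0.001 on average and flags every planted center
as spreading; the silencing regression recovers the planted −1 density
slope (mean −1.05, every planted gene negative); and the per-metacell
chromatin-transcription correlation rises along latent time (r = 0.85
between coupling and latent time), the progressive-coupling pattern the
generator plants. `analysis/04`-`06` evaluate the domain caller
(recall and precision 1.00 on 100 planted domains), the TF classifier
(16/20 TFs selected, 81-88% of selected planted TFs correctly classed,
no null TF selected), and the differential test (100% of planted 4-fold
losses detected at FDR < 0.05 and log2FC < −1).

A minimal in-session example of one stage:

```r
library(comap)
d <- simulate_spreading_metacells(n_metacells = 150, beta1 = 0.8,
                                  snr = 3, seed = 1)
spreading_regression(d$x, d$y, d$lineage)
#>      beta0     beta1 pearson_r     r_pvalue spreading_flag  lrt_stat ...
#> 1 5.425513 0.7823556 0.9525051 2.585984e-78           TRUE 0.2280959
```

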