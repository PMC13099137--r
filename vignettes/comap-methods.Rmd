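---
title: "Methods: chromatin-transcription co-mapping analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-transcription co-mapping analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

comap analyzes paired single-cell measurements of a histone modification
(antibody-targeted MNase cleavage, "ChIC") and the full-length
transcriptome from the same cells, collected along early embryonic
development. The biological questions it addresses are: how does the
repressive mark H3K27me3 spread in cis from pre-marked loci as cells
differentiate; when does that spreading silence the underlying genes; when
do active (H3K4me1) and repressive chromatin states couple to
transcription; and which transcription factors act as activators or
repressors of their target enhancers, and whether their activity is itself
chromatin-regulated. This vignette documents the models, the parameters
that matter, the synthetic-data generator the analyses are validated on,
and the numerical choices.

## Data model and containers

Counts are held in `cell_matrix` objects: a sparse cells x features
integer matrix with a modality tag (`chic`, `rna_spliced`,
`rna_unspliced`), an optional histone-mark label, and aligned cell and
feature metadata. Genomic coordinates are 0-based half-open (BED
convention) everywhere; interval-overlap computations convert to
`GenomicRanges` internally and convert back. ChIC counts live on
fixed-width genomic bins (5 kb for the spreading analysis; any width for
domain calling); RNA counts live on genes, with spliced and unspliced
counts kept as separate matrices because unspliced (intronic) signal is
the more direct readout of ongoing transcription.

## Quality control and normalization

RNA cells are kept when total counts >= 1000, detected genes <= 10000,
the fraction of counts in the cell's top-100 genes <= 0.6, and the
fraction of counts on protein-coding genes >= 0.70. ChIC cells are kept
when total MNase cuts fall in `[min_cuts, max_cuts]`; there is no
canonical value for the over-fragmentation bound, so both bounds are
configuration values (function defaults 300 and 100,000; the synthetic
pipeline uses a min of 30, scaled to the toy genome's per-cell totals —
see *Scale compression* below).

Normalization is the shifted-log variance-stabilizing transform

$$ y = \frac{1}{\sqrt{\alpha}} \log\!\left(4 \alpha \frac{x}{s} + 1\right) $$

with fixed overdispersion $\alpha = 0.05$ and size factors $s$ equal to
per-cell total counts scaled to mean 1 ("normed sum"). The log is the
natural log: the transform is derived as a variance-stabilization for
overdispersed counts and a base change only rescales every downstream
linear step. Highly variable genes are ranked by the variance of analytic
Pearson residuals $(x_{ij}-\mu_{ij})/\sqrt{\mu_{ij}+\mu_{ij}^2/\theta}$
with $\mu_{ij}$ the product of margins over the total, $\theta = 100$,
and residuals clipped to $\pm\sqrt{n_\text{cells}}$ (the standard
defaults of the analytic-residual method); the top 4000 genes are kept
by default. Genes enter the ranking only when
detected in at least min(1% of cells, 50) cells.

## ChIC latent semantic analysis

Sparse bin counts are treated as a document-term problem: cells are
documents, bins are terms. Nonzero counts are weighted by
$\mathrm{tf} = 1 + \log_2 f$ and $\mathrm{idf} = \log_2(N/n_k)$, where
$f$ is the bin count, $N$ the number of cells, and $n_k$ the number of
cells detecting the bin. Each cell's weighted vector is then divided by
the pivoted unique-normalization length
$(1-s)\,\mathrm{pivot} + s\,\mathrm{nnz}_i$, with $\mathrm{nnz}_i$ the
cell's detected-bin count, the pivot their mean over cells, and slope
$s = 0.25$. One sometimes sees this step written as a scalar affine map
of the TF-IDF value itself; that form does not depend on the cell's
detected-bin count and cannot correct for the number of detected regions
per cell, so we implement the standard pivoted unique normalization
(division by the pivoted length), which does.

The normalized matrix gets a truncated SVD (50 topics by default),
computed from the eigendecomposition of the cell-cell Gram matrix —
deterministic, no randomized solver — with topic signs fixed so each
topic's largest-magnitude cell loading is positive. Depth leakage is
removed by dropping every topic whose absolute Pearson correlation with
log total counts exceeds 0.5; on real data this is typically topic 1; a
correlation test rather than a fixed drop-the-first-topic rule also
handles synthetic data where depth loads elsewhere. At least one topic is
always retained. A Euclidean 30-nearest-neighbor graph in retained-topic
space (self excluded, union-symmetrized) is the clustering interface.
Cell vectors are not additionally L2-normalized after the pivoted
normalization.

## Metacells

Cells are pooled into metacells — pseudo-replicate observations — by
seeded k-means on a transcriptome embedding (PCA of Pearson residuals of
the highly variable genes), followed by explicit nearest-centroid
assignment. Archetype-based aggregators serve the same role on real data; since
downstream analyses only consume the assignment, any externally computed
assignment can be supplied through `metacell_set()`.
For analyses comparing the two histone marks, each metacell is balanced:
the majority mark is randomly downsampled (seeded) to the minority count
and metacells with fewer than 20 cells of either mark are dropped
entirely. Metacells are annotated with the modal cell-type label (ties
broken lexicographically and flagged), the modal timepoint, and the arithmetic mean latent
time of members. Aggregation is plain column summation over members, so
counts are conserved exactly over assigned cells.

With 2,000 cells per mark and `nc = 60` metacells, the typical metacell
holds ~30 cells of each mark before balancing, comfortably above the
20-per-mark floor; pushing `nc` much higher at this cell count empties
the balancing step.

## Domain calling

Enriched domains are called on pooled pseudo-bulk bin counts with a
two-state hidden Markov model (background / enriched) with
negative-binomial emissions, fitted by EM: weighted method-of-moments
updates for the two NB means and dispersions, expected transition counts
for the transition matrix, initial means at the 50th and 95th count
percentiles, at most 200 iterations, relative log-likelihood tolerance
1e-6, and a warning (last iterate used) on non-convergence. Posterior
decoding at 0.5 defines enriched runs; runs with mean enriched-state
posterior < 0.4 are removed (the posterior is averaged per region). This
HMM plays the role that dedicated broad-domain callers play in standard
workflows — it is not a bit-for-bit reproduction of any of them — and
the analysis-specific content, the posterior filter and the subpeak
merge rule, sits on top of it.

Subpeaks are scored inside each domain: candidate segments are maximal
runs of bins above the domain mean, scored as
$-10\log_{10} P_\text{Pois}(X \ge \text{segment sum})$ against a local
rate $\lambda$ taken as the larger of the surrounding 10-kb window mean
and the domain's own mean (so a subpeak must stand out above its parent,
not merely above the flanking background). Segments scoring >= 50 become
subpeaks, and any domain containing a subpeak is replaced by its
subpeaks; the merge rule is applied exhaustively.

Domains are classified against gene models with priority
promoter > gene-covering > genic > intergenic. The promoter window is
strand-aware, 200 bp upstream to 300 bp downstream of the TSS
(downstream-heavy, the common convention for promoter windows around a
TSS). Gene-covering means the domain
overlaps >= 80% of a gene's length. Intergenic domains are assigned their
nearest gene. Finally, two marks' domain sets are partitioned into
mark-unique and co-enriched classes by any-bp overlap.

## Cis-spreading and silencing models

**Center bins** are 5-kb bins with nonzero counts in at least 5% of
pluripotent cells (count threshold `ceiling(0.05 * n_pluripotent)`).
For each center, the **neighbor** signal is the sum over the 10 flanking
bins on each side (a 100-kb window; summing the window, rather than
modeling flanks per bin, matches the view of the flanks as one
background signal). Across metacells the model is
ordinary least squares

$$ Y_i = \beta_0 + \beta_1 X_i + \epsilon_i $$

with $X$ the center signal and $Y$ the neighbor-window signal. A center
is flagged as *spreading* when the center-neighbor Pearson correlation
exceeds 0.3 with p < 0.05 — an explicit, configurable rule for the
otherwise qualitative notion of a positively correlating bin. Lineage
specificity is tested by a likelihood-ratio test against the model with a
lineage covariate: Gaussian likelihood at the MLE variance,
$\chi^2$ with (levels − 1) degrees of freedom, BH-adjusted across center
bins. The regressions run on raw metacell-summed counts: the model is
specified on counts and the generating slope is only identifiable on the
count scale; a variance-stabilized variant can be obtained by
transforming the inputs with `shifted_log()` first.

**Silencing** regresses, across metacells,
$Y = \log_2(\text{unspliced counts} / \text{intron kb} + 1)$ on
$X = \log_2(\text{H3K27me3 counts on the gene's domain} / \text{domain kb}
+ 1)$. Both quantities are densities (counts per kb): dividing by feature
length is what makes genes of different intron lengths and domains of
different widths comparable — multiplying counts by length, which one
occasionally sees written, produces a quantity that grows with the
annotation and is not a density. The pseudocount of 1 read (configurable) is
added before the log to handle zeros. Genes with all-zero unspliced
counts or zero-variance chromatin density are excluded with a reason
code.

**Coupling** is the per-metacell Pearson correlation, across a shared
gene universe, between shifted-log gene-body mark signal and shifted-log
expression, reported against the metacell's mean latent time. Metacells
with fewer than 3 informative genes return NA.

## TF activity model

Motif-level activity is computed on H3K4me1-unique peaks (peaks
co-enriched for H3K27me3 are excluded). For each motif's peak set, the
expected counts per sample are depth x peak-popularity; the raw deviation
$(obs - exp)/exp$ is bias-corrected into a z-score against 50 background
peak sets matched on accessibility rank bins (25 bins). This is the chromVAR bias-correction idea in simplified form:
background matching uses mean accessibility only, because synthetic data
has no sequence and hence no GC dimension. Deviations are deterministic given
the seed, invariant to a global count scalar, and undefined (NA) when the
background deviations are degenerate.

Each TF's deviation vector is predicted from per-metacell features — TF
expression (shifted-log spliced counts), the TF's own gene-body H3K4me1
and H3K27me3 (log1p metacell counts), mean latent time, and lineage
one-hots — with lasso regression: a seeded 70/30 train/test split,
features standardized on the training split only, lambda chosen by
10-fold cross-validation on the training split over a 30-point log grid
with the one-SE rule (the largest lambda within one standard error of
the CV minimum — standard sparse-model reporting), and R² evaluated on
the held-out 30%.

Significance comes from permutations of the response re-run through the
identical protocol: $p = (1 + \#\{R^2_\text{perm} \ge
R^2_\text{obs}\})/(1 + n_\text{perm})$, BH-adjusted across TFs, selection
at padj < 0.01. The default permutation count is $n_\text{perm} = 200$: the add-one
estimator imposes a hard floor of $1/(n_\text{perm}+1)$ on p-values, so
with $m$ motifs of which $k$ are signal the smallest reachable adjusted
p is $\frac{m}{k(n_\text{perm}+1)}$ — at $n_\text{perm} = 100$ and 20
motifs this floor exceeds 0.01 and the selection rule could never fire;
any study selecting a minority of hundreds of motifs at padj < 0.01
likewise needs several hundred permutations. Selected TFs are classified by coefficient
signs: expression weight > 0 is an activator, < 0 a repressor, 0
unclassified; nonzero weight on the TF's own gene-body chromatin marks it
chromatin-regulated, otherwise independent. An additional reporting flag
records models with test R² > 0.6.

## Differential chromatin between cell types

Metacells are the biological replicates. Cell types with fewer than 3
metacells are dropped. Genes pass the expression filter when enough
samples reach the CPM cutoff `min.count / median(libsize) * 1e6` (the
required sample count follows the reference filter's documented rule,
with the smallest group size damped through `min.prop` above 10 samples)
and the gene's total count is at least `min.total.count`
(defaults 5 / 0.3 / 20). Normalization uses TMM factors (30% log-ratio
trim, 5% abundance trim, precision weights, geometric-mean anchored).

The per-gene test is a negative-binomial GLM likelihood-ratio test of a
one-vs-rest design (each late cell type against all other metacells
pooled; one-vs-rest treats the pooled earlier stages as the reference
state) with
log effective library size offsets. Dispersions are estimated per gene by
Cox-Reid adjusted profile likelihood given group-wise fitted means — the
adjustment corrects the downward bias of the plain profile MLE that
otherwise makes the LRT anti-conservative at 6-20 replicates — then
shrunk toward a lowess mean-dispersion trend with prior weight 10
effective degrees of freedom. The LRT with trended/tagwise Cox-Reid dispersions is this package's own
implementation; quasi-likelihood F-tests on the same design are slightly
more conservative, and the LRT's null false-positive rate here is ~6% at
nominal 5% with 8 vs 8 replicates. Fold changes are reported with a
pseudocount of 0.5 on group mean CPMs — reporting only, never in the
likelihood. Demethylated genes are those with FDR < 0.05 **and**
log2FC < −1 in their cell type, both strict.

## The synthetic-data generator

`simulate_dataset()` generates the paired dataset the whole analysis is
validated on. Defaults — the study conditions of every recovery test —
are 2,000 cells per mark, a single 25-Mb contig of 5,000 five-kb bins,
800 genes, lognormal depth factors (sdlog 0.35), and NB counts with
dispersion $\phi = 0.3$ (variance $\mu + \phi\mu^2$), matching
overdispersed single-cell counts. Cells have latent time
$t \sim U(0,1)$; cells with $t < 0.3$ are pluripotent, later cells belong
to one of 3 lineages, with mid/late stages splitting at $t = 0.65$.

Planted structure, and what recovers it:

* **Cis-spreading** (40 loci): the center bin's per-cell mean is
  $0.5 + 8t$; each of the 20 flanking bins receives extra Poisson signal
  $\beta_1 x_c / 20$ *conditional on the realized center count* $x_c$
  ($\beta_1 = 0.8$). Conditioning on the realized signal makes
  $E[Y\,|\,X] = \text{const} + \beta_1 X$ hold exactly at any
  aggregation level, so the OLS slope is unbiased for $\beta_1$ —
  generating flanks from the latent rate instead would attenuate the
  estimate through errors-in-variables, which is a property of the
  estimator, not of the planted biology.
* **Silenced genes** (60): a 20-kb domain under the gene gains H3K27me3
  density as $2^{3t}$ while the gene's unspliced rate scales as
  $(2^{3t})^{\text{slope}}$ with slope −1; the silencing regression of
  log2 unspliced density on log2 mark density recovers the slope.
* **Demethylated genes** (30): gene bodies gain H3K27me3 with development
  in all lineages except their planted lineage, where late cells lose 75%
  of it; the differential stage recovers them at FDR < 0.05, log2FC < −1.
  These genes double as the de-novo-gain background the domain caller
  sees.
* **TF programs** (20 TFs: 8 activators, 8 repressors, 4 nulls; half of
  the planted TFs chromatin-regulated): each TF owns 20 H3K4me1 peaks
  whose rates scale as $e^{0.7 a(c)}$ with the TF's activity $a$;
  activators' activity is their standardized expression program,
  repressors' its negation, nulls' an i.i.d. per-cell noise program
  (which vanishes at the metacell level, making them honest negatives).
  Regulated TFs mix 0.6 x expression with 0.8 x a hidden smooth program
  $h(t)$ — a sinusoid in latent time that a linear pseudotime feature
  cannot absorb — and their own gene-body H3K4me1 reads out $h$, so the
  lasso needs the self-chromatin feature to explain their activity.
  15% of peaks additionally gain H3K27me3 (co-enriched; exercises the
  unique-peak filter).
* **Maternal RNA** (toggle, default on): 60 genes with spliced counts
  high early (decaying $4 \cdot 2^{-3t}$) and unspliced rising later,
  emulating the maternal-to-zygotic transition.
* **Lineage markers** (40 per lineage) give the transcriptome embedding
  its branch structure.

Stage-level simulators (`simulate_spreading_metacells`,
`simulate_silencing_metacells`, `simulate_tf_metacells`,
`simulate_domain_track`) generate data directly at the scale the
corresponding model consumes, with noise parameterized the way the
recovery study states it (e.g. spreading noise at SNR 3, defined as the
sd of the signal term over the residual sd).

**Scale compression.** The toy genome is ~100x smaller than a real one
while per-cell information content is kept comparable per planted locus.
Two consequences are deliberate: per-cell ChIC totals are in the
hundreds, so the pipeline's ChIC QC floor is 30 cuts rather than the
few-hundred appropriate for genome-wide data; and background bins are
sparse (0.01 cuts/bin/cell) so that center-bin detection — a rarity
property on the real genome — remains one on 5,000 bins. What the
generator does not emulate: sequence content (hence no GC bias and no GC
background matching), batch effects, doublets, ambient contamination,
fragment-length structure, and real genomic feature geometry
(overlapping genes, nested domains). Passing recovery tests therefore
demonstrates correctness of the estimators under the generative
assumptions, not robustness to artifacts absent from the generator.

## Determinism and problem sizes

Every stochastic step takes an explicit seed; the pipeline derives
per-stage seeds by hashing the stage name with the global seed (all below
2^31). A fixed configuration and seed reproduce byte-identical result
tables. The shipped analyses run the full pipeline at the default study
size (2,000 cells/mark, 5,000 bins, 800 genes: a few minutes on one CPU);
the recovery studies use 150 metacells x 50 seeds (spreading), 2,000
simulations (LRT calibration), 100 metacells x 100 genes (silencing),
50,000 bins x 100 plants (domain caller), 120 metacells x 20 TFs with 200
permutations (classification) and 20 seeds of null TFs at 100
permutations (null calibration), and 24 metacells x 500 genes
(differential) — sizes chosen so each study's Monte-Carlo error is small
relative to the property it checks.

## Known limitations

* The domain caller is its own NB-HMM implementation; absolute posterior
  values and domain boundaries can differ from other broad-domain
  callers even where the filter-and-merge semantics match.
* The Gaussian LRT for lineage-specific spreading is asymptotic; at 150
  metacells its null rejection rate is ~5.3% at nominal 5%.
* The NB LRT is mildly liberal (~6% at nominal 5% with 8v8 replicates)
  despite the Cox-Reid adjustment; the reference quasi-likelihood F-test
  is tighter at very small replicate counts.
* Latent time is consumed as input (here, from the generator); no
  velocity or pseudotime inference is performed.
* Batch alignment across experimental batches is out of scope; the
  embedding input to the metacell stage is caller-provided.
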