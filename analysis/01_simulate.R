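#!/usr/bin/env Rscript
# Generate the synthetic paired ChIC + RNA dataset used by the whole
# analysis: 2,000 cells per histone mark on a 25-Mb toy genome (5,000
# five-kb bins, 800 genes), with planted cis-spreading loci, silenced
# genes, demethylated genes, and TF programs. Writes the ground-truth
# tables and a dataset summary under results/01_simulate/.

suppressPackageStartupMessages({
  library(comap)
  library(Matrix)
})

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
ds <- simulate_dataset(cfg)

summary_tab <- data.frame(
  modality = c("H3K27me3", "H3K4me1", "rna_spliced", "rna_unspliced"),
  n_cells = c(nrow(ds$chic_k27$counts), nrow(ds$chic_k4$counts),
              nrow(ds$rna_spliced$counts), nrow(ds$rna_unspliced$counts)),
  n_features = c(ncol(ds$chic_k27$counts), ncol(ds$chic_k4$counts),
                 ncol(ds$rna_spliced$counts),
                 ncol(ds$rna_unspliced$counts)),
  median_counts = c(median(rowSums(ds$chic_k27$counts)),
                    median(rowSums(ds$chic_k4$counts)),
                    median(rowSums(ds$rna_spliced$counts)),
                    median(rowSums(ds$rna_unspliced$counts))))
write.table(summary_tab, file.path(out, "dataset_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$truth$spreading_centers,
            file.path(out, "truth_spreading_centers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$truth$silenced_genes,
            file.path(out, "truth_silenced_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$truth$tf_classes, file.path(out, "truth_tf_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$truth$demethylated_genes,
            file.path(out, "truth_demethylated_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "Simulated %d cells per mark over %d bins and %d genes (seed %d):\n",
  cfg$n_cells_per_mark, cfg$n_bins, cfg$n_genes, cfg$seed))
cat(sprintf(
  " planted %d spreading centers (beta1 = %.1f), %d silenced genes\n",
  nrow(ds$truth$spreading_centers), cfg$spreading_slope,
  nrow(ds$truth$silenced_genes)))
cat(sprintf(
  " (slope = %.1f), %d demethylated genes, %d TFs (%d act / %d rep / %d null).\n",
  cfg$silencing_slope, nrow(ds$truth$demethylated_genes), cfg$n_tfs,
  cfg$tf_split[1], cfg$tf_split[2], cfg$tf_split[3]))
cat("Truth tables written to", out, "\n")
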