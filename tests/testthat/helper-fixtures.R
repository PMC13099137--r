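# Shared fixtures, built in code.

# small random count matrix as a cell_matrix
random_cell_matrix <- function(n_cells = 20, n_features = 15, lambda = 2,
                               modality = "chic", mark = "H3K27me3",
                               seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_features, lambda), n_cells, n_features)
  cell_matrix(counts, modality, mark)
}

# dense brute-force TF-IDF + pivoted normalization, straight from the
# printed formulas (independent of the sparse implementation)
dense_tfidf_pivoted <- function(counts, slope = 0.25) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  w <- matrix(0, n, ncol(counts))
  nnz <- rowSums(counts > 0)
  n_k <- colSums(counts > 0)
  for (i in seq_len(n)) {
    for (k in seq_len(ncol(counts))) {
      f <- counts[i, k]
      if (f > 0 && n_k[k] > 0) {
        w[i, k] <- (1 + log2(f)) * log2(n / n_k[k])
      }
    }
  }
  pivot <- mean(nnz)
  for (i in seq_len(n)) {
    w[i, ] <- w[i, ] / ((1 - slope) * pivot + slope * nnz[i])
  }
  w
}

# toy gene models on one contig
toy_genes <- function() {
  gene_models(gene_id = c("gA", "gB", "gC"),
              chrom = "chr1",
              start = c(1000, 10000, 50000),
              end = c(3000, 14000, 52000),
              strand = c("+", "-", "+"),
              tss = c(1000, 13999, 50000),
              intron_length_bp = c(500, 1500, 800))
}
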