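small_cfg <- function(seed = 1, ...) {
  sim_config(n_cells_per_mark = 150, n_bins = 2500, n_genes = 200,
             n_spreading_loci = 10, n_silenced_genes = 20, n_peaks = 150,
             n_tfs = 10, tf_split = c(4, 4, 2), seed = seed, ...)
}

test_that("a fixed seed reproduces the dataset exactly", {
  d1 <- simulate_dataset(small_cfg(seed = 3))
  d2 <- simulate_dataset(small_cfg(seed = 3))
  expect_identical(as.matrix(d1$chic_k27$counts),
                   as.matrix(d2$chic_k27$counts))
  expect_identical(as.matrix(d1$rna_unspliced$counts),
                   as.matrix(d2$rna_unspliced$counts))
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(small_cfg(seed = 4))
  expect_false(identical(as.matrix(d1$chic_k27$counts),
                         as.matrix(d3$chic_k27$counts)))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_bins = 100, n_spreading_loci = 50),
               "infeasible")
})

test_that("dataset round-trips through the on-disk layout", {
  d <- simulate_dataset(small_cfg(seed = 5))
  out <- withr::local_tempdir()
  manifest <- write_dataset(d, out)
  expect_true("manifest.tsv" %in% list.files(out))
  expect_true(all(manifest$seed == 5))
  back <- read_cell_matrix(file.path(out, "chic_k27.mtx"),
                           file.path(out, "chic_k27.barcodes.tsv"),
                           file.path(out, "chic_k27.features.tsv"),
                           meta = file.path(out, "chic_k27.cell_meta.tsv"),
                           modality = "chic", mark = "H3K27me3")
  expect_equal(as.matrix(back$counts), as.matrix(d$chic_k27$counts))
  expect_equal(back$cell_meta$latent_time, d$chic_k27$cell_meta$latent_time)

  # referential integrity of the written ground truth
  tr <- read.delim(file.path(out, "truth_silenced_genes.tsv"))
  expect_true(all(tr$gene_id %in% d$gene_models$gene_id))
  tf <- read.delim(file.path(out, "truth_tf_classes.tsv"))
  expect_true(all(tf$tf_id %in% d$gene_models$gene_id))
})

test_that("marginal count means match the configured rates", {
  # deep config so the Monte-Carlo error is small
  d <- simulate_dataset(sim_config(n_cells_per_mark = 1000, n_bins = 2000,
                                   n_genes = 200, n_spreading_loci = 5,
                                   n_silenced_genes = 10, n_peaks = 100,
                                   n_tfs = 10, tf_split = c(4, 4, 2),
                                   seed = 8))
  # spreading-center bin: per-cell mean = depth * (0.5 + 8t); compare the
  # realized mean against the generating equation within 3 standard errors
  cb <- d$truth$spreading_centers$bin[1]
  t_k <- d$chic_k27$cell_meta$latent_time
  x <- as.numeric(d$chic_k27$counts[, cb])
  mu <- mean(0.5 + 8 * t_k)  # depth has mean ~exp(sdlog^2/2), corrected below
  mu <- mu * exp(0.35^2 / 2)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu), 3 * se + 0.05 * mu)

  # NB overdispersion present: variance well above the mean
  expect_gt(var(x), 1.5 * mean(x))
})

test_that("without planted loci, center/neighbor correlations vanish", {
  d <- simulate_dataset(sim_config(n_cells_per_mark = 400, n_bins = 1500,
                                   n_genes = 150, n_spreading_loci = 0,
                                   n_silenced_genes = 10, n_peaks = 80,
                                   n_tfs = 6, tf_split = c(2, 2, 2),
                                   seed = 9))
  # aggregate cells into coarse pseudo-metacells by latent time
  t_k <- d$chic_k27$cell_meta$latent_time
  grp <- cut(t_k, 20, labels = FALSE)
  agg <- rowsum(as.matrix(d$chic_k27$counts), grp)
  # probe background bins as if they were centers
  probes <- seq(30, 1400, by = 100)
  w <- neighbor_window_counts(agg, probes)
  rs <- vapply(seq_along(probes), function(i) {
    x <- w$center[, i]; y <- w$neighbor[, i]
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.25)
})

test_that("stage-level simulators expose their planted truth", {
  d <- simulate_spreading_metacells(n_metacells = 50, beta1 = 0.8, seed = 2)
  expect_equal(nrow(d), 50)
  s <- simulate_silencing_metacells(n_metacells = 40, n_genes = 5, seed = 2)
  expect_equal(dim(s$k27), c(40L, 5L))
  tf <- simulate_tf_metacells(n_metacells = 40, n_act = 2, n_rep = 2,
                              n_null = 1, seed = 2)
  expect_equal(colnames(tf$responses), tf$truth$tf_id)
  tr <- simulate_domain_track(n_bins = 5000, n_plants = 10, seed = 2)
  expect_equal(nrow(tr$plants), 10)
  expect_true(all(tr$counts >= 0))
  expect_error(simulate_domain_track(n_bins = 100, n_plants = 10),
               "infeasible")
})
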