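test_that("center-bin detection applies the pluripotent fraction rule", {
  counts <- matrix(0, 120, 3)
  # bin 1: nonzero in exactly 5 of 100 pluripotent cells (boundary)
  counts[1:5, 1] <- 1
  # bin 2: nonzero only in the 20 non-pluripotent cells
  counts[101:120, 2] <- 3
  # bin 3: nonzero in 1 pluripotent cell
  counts[7, 3] <- 2
  mask <- c(rep(TRUE, 100), rep(FALSE, 20))
  expect_equal(find_center_bins(counts, mask, 0.05), 1L)
  # frac = 0 keeps every bin with at least one pluripotent nonzero
  expect_equal(find_center_bins(counts, mask, 0), c(1L, 3L))
  expect_error(find_center_bins(counts, rep(FALSE, 120), 0.05), "empty")
})

test_that("neighbor windows sum the 10 flanking bins each side", {
  counts <- matrix(1, 4, 30)
  w <- neighbor_window_counts(counts, centers = 15, n_neighbors = 10)
  expect_equal(unname(w$neighbor[, 1]), rep(20, 4))
  expect_equal(unname(w$center[, 1]), rep(1, 4))
  # truncated at the track edge
  w2 <- neighbor_window_counts(counts, centers = 2, n_neighbors = 10)
  expect_equal(unname(w2$neighbor[, 1]), rep(11, 4))
})

test_that("spreading regression matches the closed form and flags", {
  # identity: Y = X exactly
  x <- c(1, 3, 5, 9, 2, 8, 4, 7, 6, 10, 11, 12)
  r <- spreading_regression(x, x)
  expect_equal(r$beta1, 1)
  expect_equal(r$beta0, 0)
  expect_equal(r$pearson_r, 1)
  expect_true(r$spreading_flag)

  # closed-form OLS oracle on random data
  set.seed(20)
  xx <- rnorm(50, 10, 3); yy <- 2 + 0.5 * xx + rnorm(50)
  r2 <- spreading_regression(xx, yy)
  b1 <- cov(xx, yy) / var(xx)
  b0 <- mean(yy) - b1 * mean(xx)
  expect_equal(r2$beta1, b1, tolerance = 1e-10)
  expect_equal(r2$beta0, b0, tolerance = 1e-10)

  # zero-variance X: undefined r, flag false
  r3 <- spreading_regression(rep(5, 12), rnorm(12))
  expect_false(r3$spreading_flag)
  expect_true(is.na(r3$pearson_r))
})

test_that("planted spreading slope is recovered from the generating model", {
  hits <- 0
  for (seed in 1:10) {
    d <- simulate_spreading_metacells(n_metacells = 150, beta1 = 0.8,
                                      snr = 3, seed = seed)
    r <- spreading_regression(d$x, d$y, d$lineage)
    if (abs(r$beta1 - 0.8) <= 0.1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("lineage LRT is calibrated under the null and detects effects", {
  set.seed(31)
  # null: rejection rate near alpha (quick check; full calibration in the
  # acceptance suite)
  p <- replicate(300, {
    d <- simulate_spreading_metacells(n_metacells = 100, beta1 = 0.5,
                                      snr = 3, seed = sample.int(1e6, 1))
    spreading_regression(d$x, d$y, d$lineage)$lrt_pvalue
  })
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.12)

  # a real lineage shift is detected
  d <- simulate_spreading_metacells(n_metacells = 150, beta1 = 0.5,
                                    snr = 3, lineage_effect = 50, seed = 5)
  expect_lt(spreading_regression(d$x, d$y, d$lineage)$lrt_pvalue, 0.01)

  # LRT statistic is invariant under affine rescaling of X and Y
  d2 <- simulate_spreading_metacells(n_metacells = 80, seed = 9)
  a <- spreading_regression(d2$x, d2$y, d2$lineage)
  b <- spreading_regression(10 * d2$x + 3, -2 * d2$y + 7, d2$lineage)
  expect_equal(a$lrt_stat, b$lrt_stat, tolerance = 1e-8)
})

test_that("BH adjustment over center bins is monotone and bounded", {
  set.seed(40)
  counts <- matrix(rpois(50 * 60, 5), 50, 60)
  res <- spreading_scan(counts, centers = c(15, 30, 45),
                        lineages = factor(rep(1:2, 25)))
  ok <- !is.na(res$lrt_pvalue)
  expect_true(all(res$lrt_padj[ok] >= res$lrt_pvalue[ok]))
  expect_equal(res$lrt_padj[ok],
               p.adjust(res$lrt_pvalue[ok], "BH"))
})

test_that("silencing fit recovers the planted density slope", {
  d <- simulate_silencing_metacells(n_metacells = 100, n_genes = 30,
                                    slope = -1, seed = 3)
  slopes <- vapply(seq_len(30), function(g) {
    silencing_fit(d$unspliced[, g], d$k27[, g], d$intron_length_bp[g],
                  d$domain_length_bp[g])$slope
  }, numeric(1))
  expect_gte(mean(slopes < 0), 0.95)
  expect_lt(abs(mean(slopes) - (-1)), 0.25)
})

test_that("silencing densities are length-invariant and guarded", {
  set.seed(4)
  u <- rpois(50, 20); k <- rpois(50, 30)
  f1 <- silencing_fit(u, k, 2000, 10000)
  f2 <- silencing_fit(u, 2 * k, 2000, 20000)  # doubling counts and length
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)

  # constant chromatin -> excluded
  expect_true(silencing_fit(u, rep(7, 50), 2000, 10000)$excluded)
  # all-zero gene -> excluded with reason
  f0 <- silencing_fit(rep(0, 50), k, 2000, 10000)
  expect_true(f0$excluded)
  expect_match(f0$reason, "zero")
  expect_error(silencing_fit(u, k, 0, 1000), "intron")
})

test_that("coupling correlation behaves at the limits", {
  set.seed(50)
  rna <- matrix(rnorm(20 * 100, 5), 20, 100)
  # mark proportional to rna: r = 1 everywhere
  r1 <- coupling_correlation(3 * rna + 2, rna)
  expect_equal(r1$r, rep(1, 20), tolerance = 1e-12)
  # independent modalities: mean r near 0 at 500 genes
  rna2 <- matrix(rnorm(20 * 500), 20, 500)
  mk2 <- matrix(rnorm(20 * 500), 20, 500)
  r2 <- coupling_correlation(mk2, rna2)
  expect_lt(abs(mean(r2$r)), 0.05)
  # planted coupling increasing with latent time gives a positive trend
  t_m <- seq(0, 1, length.out = 20)
  mk3 <- sapply(seq_len(500), function(j) numeric(20))
  for (i in 1:20) {
    mk3[i, ] <- t_m[i] * rna2[i, ] + (1 - t_m[i]) * rnorm(500)
  }
  r3 <- coupling_correlation(mk3, rna2, latent_time = t_m)
  tr <- coef(lm(r3$r ~ r3$latent_time))[2]
  expect_gt(tr, 0.5)
  expect_error(coupling_correlation(rna[, 1:2], rna2[, 1:2]), "genes")
})
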