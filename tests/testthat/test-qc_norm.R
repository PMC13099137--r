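make_rna <- function(counts, biotypes = NULL) {
  ng <- ncol(counts)
  fm <- data.frame(feature_id = paste0("g", seq_len(ng)))
  cm <- cell_matrix(counts, "rna_spliced", feature_meta = fm)
  gm <- data.frame(gene_id = fm$feature_id,
                   biotype = if (is.null(biotypes))
                     rep("protein_coding", ng) else biotypes)
  list(cm = cm, gm = gm)
}

test_that("RNA QC applies all four thresholds", {
  # 200 genes so the top-100 criterion can pass for spread-out cells
  ng <- 200
  spread <- rep(10, ng)             # total 2000, top-100 frac 0.5
  low <- rep(c(5, 0), c(199, 1))    # total 995 < 1000
  onegene <- c(2000, rep(0, ng - 1))  # top-100 frac 1
  counts <- rbind(spread, low, onegene)
  x <- make_rna(counts)
  mask <- filter_cells_rna(x$cm, x$gm)
  expect_equal(unname(mask), c(TRUE, FALSE, FALSE))

  # coding fraction: 50% of counts on a non-coding gene fails the 70% cut
  bt <- rep("protein_coding", ng); bt[1] <- "lncRNA"
  half_nc <- c(1000, rep(1000 / (ng - 1), ng - 1))
  x2 <- make_rna(rbind(spread, round(half_nc)), biotypes = bt)
  mask2 <- filter_cells_rna(x2$cm, x2$gm)
  expect_false(mask2[2])

  # missing biotype column is a configuration error
  expect_error(filter_cells_rna(x$cm, data.frame(gene_id = "g1")),
               "biotype")
})

test_that("ChIC QC bounds total cuts inclusively", {
  counts <- matrix(c(250, 0, 300, 0, 500, 0), 3, 2, byrow = TRUE)
  cm <- cell_matrix(counts, "chic")
  expect_equal(unname(filter_cells_chic(cm)), c(FALSE, TRUE, TRUE))
  expect_error(filter_cells_chic(cm, min_cuts = 500, max_cuts = 400),
               "min_cuts")
})

test_that("shifted-log matches its closed form and maps zero to zero", {
  # single-cell vector with size factor 1: y = (1/sqrt(a)) ln(4a x + 1)
  p <- norm_params(alpha = 0.05)
  m <- matrix(c(0, 1, 2, 5), 1, 4)
  y <- as.matrix(shifted_log(m, p, s = 1))
  expect_equal(y[1, 1], 0)
  expect_equal(y[1, 2], (1 / sqrt(0.05)) * log(1.2), tolerance = 1e-12)
  expect_equal(round(y[1, 2], 4), 0.8154)
  # monotone: doubling x strictly increases y
  expect_true(all(diff(y[1, ]) > 0))

  # closed-form property on random inputs, including size factors
  set.seed(11)
  counts <- matrix(rpois(200, 3) + 1, 10, 20)
  s <- rowSums(counts) / mean(rowSums(counts))
  got <- as.matrix(shifted_log(counts, p))
  want <- (1 / sqrt(0.05)) * log(4 * 0.05 * sweep(counts, 1, s, "/") + 1)
  expect_lt(max(abs(got - want)), 1e-12)
  # order-preserving within each cell
  for (i in 1:10) expect_equal(order(got[i, ]), order(counts[i, ]))
})

test_that("shifted-log refuses cells with zero totals", {
  m <- matrix(c(0, 1, 0, 2), 2, 2)  # first cell has no counts
  expect_error(shifted_log(m), "zero total")
})

test_that("Pearson-residual HVG ranking finds planted variable genes", {
  set.seed(5)
  n <- 60
  flat <- matrix(rpois(n * 99, 5), n, 99)
  planted <- c(rpois(n / 2, 1), rpois(n / 2, 10))  # 10-fold two-group gene
  x <- make_rna(cbind(planted, flat))
  hv <- hvg_pearson_residuals(x$cm, norm_params(n_hvg = 10))
  expect_equal(hv$feature_id[1], "g1")

  # a gene proportional to depth has residual variance near zero and a
  # constant-depth all-equal gene is never ranked above the planted one
  depths <- rowSums(cbind(planted, flat))
  prop <- round(depths / 10)
  x2 <- make_rna(cbind(planted, prop, flat))
  hv2 <- hvg_pearson_residuals(x2$cm, norm_params(n_hvg = 101))
  expect_equal(hv2$feature_id[1], "g1")
  expect_gt(which(hv2$feature_id == "g2"), 50)

  # clamp: asking for more genes than available returns all
  expect_equal(nrow(hvg_pearson_residuals(x$cm, norm_params(n_hvg = 4000))),
               100)
  # all-zero gene ranks last with zero variance
  x3 <- make_rna(cbind(flat, zero = 0L))
  hv3 <- hvg_pearson_residuals(x3$cm, norm_params(n_hvg = 100))
  expect_equal(hv3$feature_id[100], "g100")
  expect_equal(hv3$residual_variance[100], 0)
})

test_that("QC masks are pure functions of counts (idempotent, order-free)", {
  set.seed(9)
  counts <- matrix(rpois(30 * 150, 8), 30, 150)
  x <- make_rna(counts)
  m1 <- filter_cells_rna(x$cm, x$gm, min_total = 1000)
  m2 <- filter_cells_rna(x$cm, x$gm, min_total = 1000)
  expect_identical(m1, m2)
  perm <- sample(30)
  xp <- make_rna(counts[perm, ])
  mp <- filter_cells_rna(xp$cm, xp$gm, min_total = 1000)
  expect_identical(unname(mp), unname(m1[perm]))
})
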