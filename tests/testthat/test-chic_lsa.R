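test_that("TF-IDF weighting evaluates the printed formulas", {
  # f=1 in a bin present in N/2 cells -> (1+0)*1 = 1
  counts <- matrix(0, 8, 3)
  counts[1:4, 1] <- 1
  counts[1, 2] <- 4          # f=4, n_k=2, N=8 -> (1+2)*2 = 6
  counts[2, 2] <- 1
  counts[, 3] <- 3           # present in all cells -> idf 0
  w <- tfidf_weight(cell_matrix(counts, "chic"))
  expect_equal(w[1, 1], 1)
  expect_equal(w[1, 2], 6)
  expect_true(all(w[, 3] == 0))
  # zeros stay zero
  expect_equal(w[5, 1], 0)
})

test_that("pivoted normalization divides by the pivoted length", {
  # 2 cells with nnz {10, 30}, slope 0.25 -> pivot 20, divisors 17.5, 22.5
  counts <- matrix(0, 2, 40)
  counts[1, 1:10] <- 2
  counts[2, 11:40] <- 2
  w <- Matrix::Matrix(counts, sparse = TRUE)
  nw <- pivoted_normalize(w, lsa_params(slope = 0.25))
  expect_equal(attr(nw, "pivot"), 20)
  expect_equal(nw[1, 1], 2 / 17.5)
  expect_equal(nw[2, 11], 2 / 22.5)

  # slope = 1: pure per-cell normalization by nnz
  nw1 <- pivoted_normalize(w, lsa_params(slope = 1))
  expect_equal(nw1[1, 1], 2 / 10)
  expect_equal(nw1[2, 11], 2 / 30)

  # slope -> 0 limit: global scaling by the pivot (relative geometry kept)
  nw0 <- pivoted_normalize(w, lsa_params(slope = 1e-9))
  expect_equal(nw0[1, 1] / nw0[2, 11], 1, tolerance = 1e-6)
})

test_that("weighting + normalization match a dense brute force", {
  for (seed in 1:50) {
    set.seed(seed)
    counts <- matrix(rpois(20 * 15, 1.5), 20, 15)
    counts[rowSums(counts) == 0, 1] <- 1  # no empty cells
    cm <- cell_matrix(counts, "chic")
    w <- tfidf_weight(cm)
    nw <- pivoted_normalize(w, lsa_params(slope = 0.25),
                            nnz = rowSums(counts > 0))
    want <- dense_tfidf_pivoted(counts, slope = 0.25)
    expect_lt(max(abs(as.matrix(nw) - want)), 1e-10)
  }
})

test_that("truncated SVD is exact on low-rank input and checks dims", {
  set.seed(2)
  A <- matrix(rnorm(30 * 2), 30, 2) %*% matrix(rnorm(2 * 50), 2, 50)
  r <- lsa_embed(Matrix::Matrix(A, sparse = TRUE), lsa_params(n_topics = 2))
  recon <- r$cell_topics %*% t(r$region_topics)
  expect_lt(max(abs(recon - A)), 1e-8)
  expect_true(all(diff(r$singular_values) <= 1e-8))

  # cell_topics row norms equal projection norms (oracle: dense svd)
  sv <- svd(A)
  expect_equal(sort(rowSums(r$cell_topics^2)),
               sort(rowSums((sv$u[, 1:2] %*% diag(sv$d[1:2]))^2)),
               tolerance = 1e-8)

  expect_error(lsa_embed(Matrix::Matrix(matrix(1, 40, 60), sparse = TRUE),
                         lsa_params(n_topics = 50)), "n_topics")
})

test_that("depth-correlated topics are identified and dropped", {
  # construct an embedding whose first component is exactly log depth
  set.seed(4)
  n <- 100
  depths <- round(exp(rnorm(n, 5, 0.8)))
  r <- structure(list(cell_topics = cbind(log(depths),
                                          rnorm(n), rnorm(n)),
                      region_topics = matrix(rnorm(30), 10, 3),
                      singular_values = c(3, 2, 1),
                      dropped_topics = integer(0), pivot = 1),
                 class = "lsa_result")
  r2 <- drop_depth_topics(r, depths, lsa_params(depth_corr_threshold = 0.5))
  expect_equal(r2$dropped_topics, 1L)
  expect_equal(ncol(r2$cell_topics), 2L)

  # constant depth: correlation treated as 0, nothing dropped
  r3 <- drop_depth_topics(r, rep(100, n),
                          lsa_params(depth_corr_threshold = 0.5))
  expect_equal(r3$dropped_topics, integer(0))

  # threshold 1 drops nothing
  r4 <- drop_depth_topics(r, depths, lsa_params(depth_corr_threshold = 1))
  expect_equal(r4$dropped_topics, integer(0))

  # residual correlation bound holds after dropping
  lam <- abs(cor(r2$cell_topics[, 1], log(depths)))
  expect_lte(lam, 0.5)
})

test_that("kNN graph respects geometry", {
  set.seed(6)
  # two well-separated blobs: >= 95% of edges intra-blob
  blob <- rbind(matrix(rnorm(60 * 2), 60, 2),
                matrix(rnorm(60 * 2, 20), 60, 2))
  g <- knn_graph(blob, lsa_params(k_neighbors = 10))
  same <- (g$edges$from <= 60) == (g$edges$to <= 60)
  expect_gte(mean(same), 0.95)

  # k=1 on 3 collinear equidistant points: endpoints link the middle
  pts <- matrix(c(0, 0, 1, 0, 2, 0), 3, 2, byrow = TRUE)
  g1 <- knn_graph(pts, lsa_params(k_neighbors = 1))
  expect_equal(g1$knn[1, 1], 2L)
  expect_equal(g1$knn[3, 1], 2L)

  # duplicated coordinates are mutual neighbors
  dup <- rbind(c(0, 0), c(0, 0), c(5, 5))
  g2 <- knn_graph(dup, lsa_params(k_neighbors = 1))
  expect_equal(g2$knn[1, 1], 2L)
  expect_equal(g2$knn[2, 1], 1L)

  expect_error(knn_graph(pts, lsa_params(k_neighbors = 3)), "k_neighbors")
})

test_that("embedding is invariant to cell order (up to row permutation)", {
  set.seed(8)
  counts <- matrix(rpois(40 * 30, 2), 40, 30)
  counts[rowSums(counts) == 0, 1] <- 1
  cm <- cell_matrix(counts, "chic")
  p <- lsa_params(n_topics = 5, depth_corr_threshold = 1)
  r1 <- embed_chic(cm, p)
  perm <- sample(40)
  cmp <- cell_matrix(counts[perm, ], "chic")
  r2 <- embed_chic(cmp, p)
  expect_equal(abs(r2$cell_topics), abs(r1$cell_topics[perm, ]),
               tolerance = 1e-6)
})
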