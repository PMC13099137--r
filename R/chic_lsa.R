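# Latent semantic analysis of sparse ChIC bin counts.
#
# Cells are treated as documents and genomic bins as terms: counts are
# weighted with log term frequency tf = 1 + log2(f) and inverse document
# frequency idf = log2(N / n_k), then each cell vector is divided by the
# pivoted unique-normalization length (1 - slope) * pivot + slope * nnz_i,
# where nnz_i is the cell's number of detected bins and the pivot is the
# mean of nnz over cells. A truncated SVD yields cell x topic and
# region x topic matrices; topics correlating with log depth are dropped
# before building the kNN graph.

#' LSA embedding parameters
#'
#' @param slope pivoted-normalization slope in (0, 1].
#' @param n_topics number of SVD components.
#' @param k_neighbors neighbors for the kNN graph.
#' @param depth_corr_threshold absolute Pearson correlation with log depth
#'   above which a topic is dropped.
#' @return list of class `lsa_params`.
#' @export
lsa_params <- function(slope = 0.25, n_topics = 50, k_neighbors = 30,
                       depth_corr_threshold = 0.5) {
  if (slope <= 0 || slope > 1) stop("slope must be in (0, 1]")
  structure(list(slope = slope, n_topics = n_topics,
                 k_neighbors = k_neighbors,
                 depth_corr_threshold = depth_corr_threshold),
            class = "lsa_params")
}

#' Log-TF x IDF weighting of a cells x bins count matrix
#'
#' Nonzero count f of a bin detected in n_k of N cells maps to
#' (1 + log2 f) * log2(N / n_k); zeros stay zero. A bin present in every
#' cell gets weight 0 (idf = 0).
#'
#' @param m `cell_matrix` or sparse count matrix (cells x bins).
#' @return sparse real matrix with the same sparsity pattern (up to
#'   idf-zeroed columns).
#' @export
tfidf_weight <- function(m) {
  counts <- if (inherits(m, "cell_matrix")) m$counts else m
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  n_cells <- nrow(counts)
  if (n_cells < 2) stop("need >= 2 cells")
  n_k <- Matrix::colSums(counts > 0)
  idf <- ifelse(n_k > 0, log2(n_cells / n_k), 0)
  w <- counts
  bin_of <- rep(seq_len(ncol(w)), diff(w@p))  # CSC: column index per slot
  w@x <- (1 + log2(w@x)) * idf[bin_of]
  Matrix::drop0(w)
}

#' Pivoted unique normalization of a weighted matrix
#'
#' Divides cell i's vector by d_i = (1 - slope) * pivot + slope * nnz_i,
#' where nnz_i is the cell's non-zero bin count in the *original* counts
#' and pivot = mean(nnz). With slope = 1 this is pure per-cell length
#' normalization; with slope = 0 a global rescaling.
#'
#' @param w sparse weighted matrix from [tfidf_weight()].
#' @param params `lsa_params`.
#' @param nnz optional per-cell non-zero counts (defaults to nnz of `w`).
#' @return normalized sparse matrix; attribute "pivot" records the pivot.
#' @export
pivoted_normalize <- function(w, params = lsa_params(), nnz = NULL) {
  w <- methods::as(methods::as(w, "CsparseMatrix"), "generalMatrix")
  if (is.null(nnz)) {
    wt <- Matrix::t(w)
    nnz <- diff(wt@p)
  }
  if (any(nnz == 0)) stop("cells with no detected bins must be filtered first")
  pivot <- mean(nnz)
  d <- (1 - params$slope) * pivot + params$slope * nnz
  out <- Matrix::Diagonal(x = 1 / d) %*% w
  out <- methods::as(out, "CsparseMatrix")
  attr(out, "pivot") <- pivot
  out
}

#' Truncated SVD of the normalized matrix
#'
#' Computes the rank-`n_topics` SVD via the eigendecomposition of the cell
#' Gram matrix (deterministic; sign fixed so each topic's largest-magnitude
#' cell loading is positive). `cell_topics = U %*% diag(sv)`,
#' `region_topics = V`.
#'
#' @param nw normalized sparse matrix (cells x bins).
#' @param params `lsa_params`.
#' @return list of class `lsa_result` with cell_topics, region_topics,
#'   singular_values, dropped_topics (empty), pivot.
#' @export
lsa_embed <- function(nw, params = lsa_params()) {
  k <- params$n_topics
  if (k > min(dim(nw))) stop("n_topics exceeds matrix rank bound")
  gram <- as.matrix(Matrix::tcrossprod(nw))  # cells x cells
  eig <- eigen(gram, symmetric = TRUE)
  sv <- sqrt(pmax(eig$values[seq_len(k)], 0))
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  # fix signs deterministically
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  V <- as.matrix(Matrix::crossprod(nw, U))
  pos <- sv > 1e-12
  V[, pos] <- sweep(V[, pos, drop = FALSE], 2, sv[pos], "/")
  V[, !pos] <- 0
  structure(list(cell_topics = U %*% diag(sv, nrow = k),
                 region_topics = V,
                 singular_values = sv,
                 dropped_topics = integer(0),
                 pivot = attr(nw, "pivot")),
            class = "lsa_result")
}

#' Drop topics correlated with sequencing depth
#'
#' Removes topics whose absolute Pearson correlation with log total counts
#' exceeds the threshold (the usual culprit being topic 1). At least one
#' topic is always retained. Constant depth yields correlation 0 (nothing
#' dropped).
#'
#' @param r `lsa_result`.
#' @param depths per-cell total counts.
#' @param params `lsa_params`.
#' @return `lsa_result` with offending topic columns removed and their
#'   original indices recorded in `dropped_topics`.
#' @export
drop_depth_topics <- function(r, depths, params = lsa_params()) {
  ld <- log(depths)
  corr <- apply(r$cell_topics, 2, function(z) {
    if (stats::sd(z) == 0 || stats::sd(ld) == 0) return(0)
    stats::cor(z, ld)
  })
  drop <- which(abs(corr) > params$depth_corr_threshold)
  if (length(drop) == ncol(r$cell_topics)) {
    warning("all topics correlate with depth; keeping all but the worst")
    drop <- which.max(abs(corr))
  }
  if (length(drop)) {
    r$cell_topics <- r$cell_topics[, -drop, drop = FALSE]
    r$region_topics <- r$region_topics[, -drop, drop = FALSE]
    r$singular_values <- r$singular_values[-drop]
  }
  r$dropped_topics <- as.integer(drop)
  r
}

#' Euclidean k-nearest-neighbor graph in topic space
#'
#' Self is excluded; the adjacency is symmetrized by union. Ties are broken
#' by index order.
#'
#' @param r `lsa_result` (or a plain embedding matrix, cells x dims).
#' @param params `lsa_params`.
#' @return list with `edges` (data.frame from, to, dist; from < to after
#'   union) and `knn` (cells x k matrix of neighbor indices).
#' @export
knn_graph <- function(r, params = lsa_params()) {
  emb <- if (inherits(r, "lsa_result")) r$cell_topics else r
  n <- nrow(emb)
  k <- params$k_neighbors
  if (k >= n) stop("k_neighbors must be < number of cells")
  d2 <- as.matrix(stats::dist(emb))
  diag(d2) <- Inf
  ord <- apply(d2, 1, function(row) order(row)[seq_len(k)])
  knn <- matrix(as.integer(ord), nrow = n, ncol = k, byrow = TRUE)
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(knn))
  dd <- d2[cbind(from, to)]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b)
  keep <- !duplicated(key)
  list(edges = data.frame(from = a[keep], to = b[keep], dist = dd[keep]),
       knn = knn)
}

#' ChIC embedding pipeline: weight, normalize, SVD, depth-topic drop
#'
#' @param m chic `cell_matrix`.
#' @param params `lsa_params`.
#' @return `lsa_result` after depth-topic removal.
#' @export
embed_chic <- function(m, params = lsa_params()) {
  w <- tfidf_weight(m)
  nnz <- Matrix::rowSums(m$counts > 0)
  nw <- pivoted_normalize(w, params, nnz = nnz)
  r <- lsa_embed(nw, params)
  drop_depth_topics(r, Matrix::rowSums(m$counts), params)
}
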