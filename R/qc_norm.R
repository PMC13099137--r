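# Cell-level QC and count normalization.
#
# RNA QC applies fixed thresholds (total counts, detected genes,
# top-100-gene concentration, protein-coding fraction); ChIC QC bounds the
# number of MNase cuts per cell. Normalization is the shifted-log
# variance-stabilizing transform y = 1/sqrt(alpha) * log(4*alpha*x/s + 1)
# with library-size factors s scaled to mean 1, and highly variable genes
# are ranked by the variance of analytic Pearson residuals.

#' Normalization parameters
#'
#' @param alpha fixed overdispersion of the shifted-log transform (> 0).
#' @param hvg_theta NB dispersion parameter (theta, i.e. 1/phi) used in the
#'   analytic Pearson residual; large theta approaches Poisson.
#' @param n_hvg number of highly variable genes to return.
#' @return list of class `norm_params`.
#' @export
norm_params <- function(alpha = 0.05, hvg_theta = 100, n_hvg = 4000) {
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(alpha = alpha, hvg_theta = hvg_theta, n_hvg = n_hvg,
                 size_factor_mode = "normed_sum"), class = "norm_params")
}

#' RNA cell quality filter
#'
#' Keeps a cell iff: total counts >= 1000, number of detected genes
#' <= 10000, fraction of counts in the cell's top-100 genes <= 0.6, and
#' fraction of counts on protein-coding genes >= 0.70.
#'
#' @param m RNA `cell_matrix`.
#' @param gene_models gene model table with `gene_id` and `biotype`;
#'   features of `m` are matched by feature_id.
#' @param min_total,max_genes,max_top100_frac,min_coding_frac thresholds.
#' @return logical mask over cells.
#' @export
filter_cells_rna <- function(m, gene_models, min_total = 1000,
                             max_genes = 10000, max_top100_frac = 0.6,
                             min_coding_frac = 0.70) {
  if (!m$modality %in% c("rna_spliced", "rna_unspliced"))
    stop("filter_cells_rna expects an RNA modality")
  if (!"biotype" %in% names(gene_models))
    stop("gene_models must carry a 'biotype' column")
  counts <- m$counts
  total <- Matrix::rowSums(counts)
  ngene <- Matrix::rowSums(counts > 0)
  biotype <- gene_models$biotype[match(m$feature_meta$feature_id,
                                       gene_models$gene_id)]
  coding <- !is.na(biotype) & biotype == "protein_coding"
  coding_frac <- Matrix::rowSums(counts[, coding, drop = FALSE]) / pmax(total, 1)
  tm <- Matrix::t(counts)  # CSC over cells for fast per-cell slot access
  cell_of <- rep(seq_len(ncol(tm)), diff(tm@p))
  vals <- split(tm@x, factor(cell_of, levels = seq_len(nrow(counts))))
  top100 <- vapply(vals, function(x) {
    if (!length(x)) return(0)
    sum(sort(x, decreasing = TRUE)[seq_len(min(100, length(x)))])
  }, numeric(1))
  top100_frac <- top100 / pmax(total, 1)
  total >= min_total & ngene <= max_genes &
    top100_frac <= max_top100_frac & coding_frac >= min_coding_frac
}

#' ChIC cell quality filter
#'
#' Bounds the per-cell number of MNase cuts: low-count cells carry too
#' little signal, very high counts flag over-fragmented cells. The
#' thresholds are inclusive on both sides.
#'
#' @param m chic `cell_matrix`.
#' @param min_cuts,max_cuts inclusive bounds on total cuts per cell.
#' @return logical mask over cells.
#' @export
filter_cells_chic <- function(m, min_cuts = 300, max_cuts = 100000) {
  if (m$modality != "chic") stop("filter_cells_chic expects a chic matrix")
  if (min_cuts >= max_cuts) stop("min_cuts must be < max_cuts")
  total <- Matrix::rowSums(m$counts)
  total >= min_cuts & total <= max_cuts
}

#' Library-size factors: total counts scaled to mean 1
#' @param m cell_matrix (or raw matrix of counts, cells x features).
#' @return numeric size factor per cell.
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "cell_matrix")) m$counts else m
  total <- Matrix::rowSums(counts)
  if (any(total == 0)) stop("cells with zero total counts must be filtered first")
  total / mean(total)
}

#' Shifted-log variance-stabilizing transform
#'
#' y = (1/sqrt(alpha)) * log(4*alpha*(x/s) + 1), natural log, with s the
#' per-cell size factor (total counts scaled to mean 1). Zeros map to zero
#' and the transform is monotone per cell.
#'
#' @param m `cell_matrix` or numeric/sparse matrix (cells x features).
#' @param params `norm_params`.
#' @param s optional pre-computed size factors (mean 1).
#' @return sparse matrix of normalized values with the input's dimensions.
#' @export
shifted_log <- function(m, params = norm_params(), s = NULL) {
  counts <- if (inherits(m, "cell_matrix")) m$counts else m
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(s)) s <- size_factors(counts)
  a <- params$alpha
  # operate on the nonzero slots only; the transform fixes 0
  out <- Matrix::t(counts)  # CSC over cells for slot-wise row scaling
  cell_of <- rep(seq_len(ncol(out)), diff(out@p))
  out@x <- (1 / sqrt(a)) * log(4 * a * (out@x / s[cell_of]) + 1)
  Matrix::t(out)
}

#' Gene-presence filter preceding HVG selection
#'
#' Keeps genes detected in at least min(1% of cells, 50) cells.
#'
#' @param m RNA `cell_matrix`.
#' @return logical mask over genes.
#' @export
filter_genes_presence <- function(m) {
  ncells_with <- Matrix::colSums(m$counts > 0)
  ncells_with >= min(ceiling(0.01 * nrow(m$counts)), 50)
}

#' Rank genes by analytic Pearson residual variance
#'
#' Residual r_ij = (x_ij - mu_ij) / sqrt(mu_ij + mu_ij^2/theta) with
#' mu_ij = rowsum_i * colsum_j / total, clipped to +/- sqrt(n_cells).
#' Genes are ranked by residual variance; the top `n_hvg` are returned.
#' All-zero genes have residual 0 and rank last.
#'
#' @param m RNA `cell_matrix`.
#' @param params `norm_params`.
#' @return data.frame (feature_id, residual_variance, rank) of the top
#'   `n_hvg` genes, ordered by decreasing variance.
#' @export
hvg_pearson_residuals <- function(m, params = norm_params()) {
  counts <- m$counts
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need >= 2 cells and >= 2 genes")
  rs <- Matrix::rowSums(counts)
  cs <- Matrix::colSums(counts)
  tot <- sum(rs)
  clip <- sqrt(nrow(counts))
  theta <- params$hvg_theta
  resvar <- vapply(seq_len(ncol(counts)), function(j) {
    mu <- rs * cs[j] / tot
    r <- (counts[, j] - mu) / sqrt(mu + mu^2 / theta)
    r[is.nan(r)] <- 0
    r <- pmin(pmax(r, -clip), clip)
    # population variance around 0-mean model is not assumed; use sample var
    stats::var(r)
  }, numeric(1))
  resvar[cs == 0] <- 0
  ord <- order(resvar, decreasing = TRUE)
  keep <- ord[seq_len(min(params$n_hvg, ncol(counts)))]
  data.frame(feature_id = m$feature_meta$feature_id[keep],
             residual_variance = resvar[keep],
             rank = seq_along(keep))
}

#' Compute Pearson residual matrix (dense) for selected genes
#'
#' Same residual definition as [hvg_pearson_residuals()]; used as PCA input
#' for transcriptome embedding.
#'
#' @param m RNA `cell_matrix`.
#' @param features feature ids to use (defaults to all).
#' @param params `norm_params`.
#' @return dense matrix cells x features of clipped residuals.
#' @export
pearson_residual_matrix <- function(m, features = NULL,
                                    params = norm_params()) {
  counts <- m$counts
  if (!is.null(features)) {
    idx <- match(features, m$feature_meta$feature_id)
    counts <- counts[, idx, drop = FALSE]
  }
  rs <- Matrix::rowSums(m$counts)
  cs <- Matrix::colSums(counts)
  tot <- sum(Matrix::colSums(m$counts))
  clip <- sqrt(nrow(counts))
  mu <- outer(rs, cs) / tot
  r <- (as.matrix(counts) - mu) / sqrt(mu + mu^2 / params$hvg_theta)
  r[is.nan(r)] <- 0
  pmin(pmax(r, -clip), clip)
}
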