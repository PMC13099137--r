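# Cis-spreading and gene-silencing models over metacells.
#
# Center bins are 5-kb bins with H3K27me3 signal in >= 5% of pluripotent
# cells. For each center, the summed signal of the 10 flanking bins on each
# side (a 100-kb window) is regressed on the center signal across
# metacells: Y = b0 + b1 * X. A positive, significant Pearson correlation
# flags cis-spreading; a likelihood-ratio test against a model with a
# lineage covariate asks whether the spread is lineage-specific.
# Gene silencing regresses log2 unspliced-count density (per kb intron) on
# log2 H3K27me3 density (per kb of the gene's domain) across metacells.
# Chromatin-transcription coupling is the per-metacell Pearson correlation
# between gene-body mark signal and expression across genes.

#' Identify center bins from pluripotent cells
#'
#' A bin qualifies when it has nonzero counts in at least
#' `ceiling(frac * n_pluripotent)` pluripotent cells.
#'
#' @param m chic `cell_matrix` on 5-kb bins (single cells).
#' @param pluripotent_mask logical per cell.
#' @param frac minimum detection fraction (default 0.05).
#' @return integer vector of bin (column) indices.
#' @export
find_center_bins <- function(m, pluripotent_mask, frac = 0.05) {
  counts <- if (inherits(m, "cell_matrix")) m$counts else m
  if (!any(pluripotent_mask)) stop("pluripotent mask is empty")
  sub <- counts[pluripotent_mask, , drop = FALSE]
  need <- ceiling(frac * sum(pluripotent_mask))
  which(Matrix::colSums(sub > 0) >= max(need, 1))
}

#' Sum neighbor-bin counts around center bins
#'
#' @param counts metacell x bin matrix.
#' @param centers center bin indices.
#' @param n_neighbors flanking bins on each side (default 10).
#' @return list with `center` (metacell x center matrix) and `neighbor`
#'   (summed flanking counts, same shape).
#' @export
neighbor_window_counts <- function(counts, centers, n_neighbors = 10) {
  nb <- ncol(counts)
  cen <- counts[, centers, drop = FALSE]
  nei <- vapply(centers, function(cb) {
    idx <- setdiff(max(1, cb - n_neighbors):min(nb, cb + n_neighbors), cb)
    rowSums(counts[, idx, drop = FALSE])
  }, numeric(nrow(counts)))
  nei <- matrix(nei, nrow = nrow(counts))
  colnames(cen) <- colnames(nei) <- as.character(centers)
  list(center = cen, neighbor = nei)
}

# Gaussian log-likelihood of an lm fit at the MLE variance
.gauss_ll <- function(resid, n) {
  s2 <- sum(resid^2) / n
  -n / 2 * (log(2 * pi * s2) + 1)
}

#' Cis-spreading regression for one center bin
#'
#' OLS of neighbor-window counts on center counts across metacells, the
#' center-neighbor Pearson correlation with its p-value, a spreading flag
#' (r > `r_threshold` and p < 0.05), and a likelihood-ratio test of a model
#' adding a lineage covariate (chi-squared, df = levels - 1, Gaussian
#' likelihood with MLE variance).
#'
#' @param center_counts per-metacell center-bin signal (X).
#' @param neighbor_counts per-metacell summed flanking signal (Y).
#' @param lineages factor per metacell (optional; LRT skipped if NULL).
#' @param r_threshold correlation cutoff for the spreading flag.
#' @return one-row data.frame (beta0, beta1, pearson_r, r_pvalue,
#'   spreading_flag, lrt_stat, lrt_df, lrt_pvalue).
#' @export
spreading_regression <- function(center_counts, neighbor_counts,
                                 lineages = NULL, r_threshold = 0.3) {
  x <- as.numeric(center_counts); y <- as.numeric(neighbor_counts)
  n <- length(x)
  if (n < 10) stop("need >= 10 metacells")
  if (stats::sd(x) == 0) {
    return(data.frame(beta0 = NA_real_, beta1 = NA_real_,
                      pearson_r = NA_real_, r_pvalue = NA_real_,
                      spreading_flag = FALSE, lrt_stat = NA_real_,
                      lrt_df = NA_integer_, lrt_pvalue = NA_real_))
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate); rp <- ct$p.value
  out <- data.frame(beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
                    pearson_r = r, r_pvalue = rp,
                    spreading_flag = (r > r_threshold && rp < 0.05),
                    lrt_stat = NA_real_, lrt_df = NA_integer_,
                    lrt_pvalue = NA_real_)
  if (!is.null(lineages)) {
    lin <- droplevels(as.factor(lineages))
    if (nlevels(lin) >= 2) {
      fit2 <- stats::lm(y ~ x + lin)
      ll1 <- .gauss_ll(stats::residuals(fit), n)
      ll2 <- .gauss_ll(stats::residuals(fit2), n)
      stat <- max(2 * (ll2 - ll1), 0)
      df <- nlevels(lin) - 1L
      out$lrt_stat <- stat
      out$lrt_df <- df
      out$lrt_pvalue <- stats::pchisq(stat, df, lower.tail = FALSE)
    }
  }
  out
}

#' Spreading analysis over all center bins
#'
#' Runs [spreading_regression()] per center bin and BH-adjusts the lineage
#' LRT p-values across bins.
#'
#' @param counts metacell x bin matrix (5-kb bins).
#' @param centers center bin indices.
#' @param lineages factor per metacell.
#' @param n_neighbors flanking bins each side.
#' @param r_threshold correlation cutoff for the spreading flag.
#' @return data.frame, one row per center bin, with `center_bin` and
#'   `lrt_padj` columns added.
#' @export
spreading_scan <- function(counts, centers, lineages = NULL,
                           n_neighbors = 10, r_threshold = 0.3) {
  wins <- neighbor_window_counts(counts, centers, n_neighbors)
  res <- do.call(rbind, lapply(seq_along(centers), function(i) {
    spreading_regression(wins$center[, i], wins$neighbor[, i],
                         lineages, r_threshold)
  }))
  res$center_bin <- centers
  res$lrt_padj <- stats::p.adjust(res$lrt_pvalue, method = "BH")
  res[, c("center_bin", setdiff(names(res), "center_bin"))]
}

#' Gene-silencing density regression
#'
#' Per metacell, Y = log2(unspliced counts / (intron kb) + pc) and
#' X = log2(H3K27me3 counts on the gene's domain / (domain kb) + pc);
#' the OLS slope across metacells measures how transcription decays with
#' repressive-mark density.
#'
#' @param unspliced_counts per-metacell unspliced counts of the gene.
#' @param k27_counts per-metacell H3K27me3 counts on the assigned domain.
#' @param intron_length_bp total intron length of the gene (> 0).
#' @param domain_length_bp length of the domain (> 0).
#' @param pseudocount added to both densities before log2 (default 1).
#' @return one-row data.frame (slope, intercept, r2, pvalue, excluded,
#'   reason).
#' @export
silencing_fit <- function(unspliced_counts, k27_counts, intron_length_bp,
                          domain_length_bp, pseudocount = 1) {
  if (intron_length_bp <= 0) stop("intron_length_bp must be > 0")
  if (domain_length_bp <= 0) stop("domain_length_bp must be > 0")
  empty <- function(reason) data.frame(slope = NA_real_,
                                       intercept = NA_real_, r2 = NA_real_,
                                       pvalue = NA_real_, excluded = TRUE,
                                       reason = reason)
  if (all(unspliced_counts == 0)) return(empty("all-zero gene"))
  x <- log2(k27_counts / (domain_length_bp / 1000) + pseudocount)
  y <- log2(unspliced_counts / (intron_length_bp / 1000) + pseudocount)
  if (stats::sd(x) == 0) return(empty("zero-variance chromatin density"))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  data.frame(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             r2 = sm$r.squared, pvalue = sm$coefficients[2, 4],
             excluded = FALSE, reason = NA_character_)
}

#' Per-metacell chromatin-transcription coupling correlation
#'
#' One Pearson correlation per metacell between gene-body mark signal and
#' expression across a shared gene universe (both inputs expected on a
#' comparable normalized scale). Metacells with fewer than 3 genes with
#' variation are returned as NA.
#'
#' @param mark_counts metacell x gene matrix of (normalized) mark signal.
#' @param rna_counts metacell x gene matrix of (normalized) expression.
#' @param latent_time optional per-metacell mean latent time, copied to the
#'   output for trend analysis.
#' @return data.frame (metacell, r, n_genes[, latent_time]).
#' @export
coupling_correlation <- function(mark_counts, rna_counts,
                                 latent_time = NULL) {
  stopifnot(all(dim(mark_counts) == dim(rna_counts)))
  if (ncol(mark_counts) < 3) stop("need >= 3 shared genes")
  r <- vapply(seq_len(nrow(mark_counts)), function(i) {
    a <- mark_counts[i, ]; b <- rna_counts[i, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  out <- data.frame(metacell = seq_len(nrow(mark_counts)), r = r,
                    n_genes = ncol(mark_counts))
  if (!is.null(latent_time)) out$latent_time <- latent_time
  out
}
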