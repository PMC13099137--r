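# Differential chromatin signal between cell types, using metacells as
# biological replicates. Counts are normalized with TMM factors
# (trimmed mean of M-values, geometric-mean anchored), genes are
# pre-filtered with the standard expression filter (CPM cutoff derived
# from min.count and the median library size, minimum total count), and
# each gene is tested with a negative-binomial GLM likelihood-ratio test
# (one-vs-rest design) using tagwise dispersions shrunk toward a fitted
# mean-dispersion trend. Demethylated genes are those with FDR < 0.05 and
# log2 fold change < -1 in the target cell type.

#' Retain cell types with enough metacell replicates
#'
#' @param ms annotated `metacell_set` (or a character vector of per-
#'   metacell labels).
#' @param min_metacells minimum replicates per cell type (default 3).
#' @return character vector of retained cell types.
#' @export
filter_celltypes <- function(ms, min_metacells = 3) {
  labels <- if (inherits(ms, "metacell_set")) {
    stopifnot(!is.null(ms$annotations))
    ms$annotations$label[ms$annotations$n_cells > 0]
  } else as.character(ms)
  tab <- table(labels)
  out <- names(tab)[tab >= min_metacells]
  if (!length(out)) warning("no cell type has enough metacells")
  out
}

#' Expression filter for count matrices
#'
#' Follows the standard filterByExpr rule: a gene is kept when (a) at
#' least `MinSampleSize` samples have CPM >= min_count/median(libsize)*1e6,
#' where MinSampleSize is the smallest group size (damped through
#' `min_prop` above `large_n` samples), and (b) its total count is at
#' least `min_total`.
#'
#' @param counts sample x gene matrix (samples are metacells).
#' @param groups factor per sample.
#' @param min_count,min_total,min_prop,large_n filter parameters.
#' @return logical mask over genes.
#' @export
filter_by_expression <- function(counts, groups, min_count = 5,
                                 min_total = 20, min_prop = 0.3,
                                 large_n = 10) {
  counts <- as.matrix(counts)
  lib <- rowSums(counts)
  cpm_cutoff <- min_count / stats::median(lib) * 1e6
  min_n <- min(table(groups))
  if (min_n > large_n) min_n <- large_n + (min_n - large_n) * min_prop
  cpm <- counts / lib * 1e6
  tol <- 1e-14
  keep_cpm <- colSums(cpm >= cpm_cutoff) >= (min_n - tol)
  keep_total <- colSums(counts) >= (min_total - tol)
  keep_cpm & keep_total
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values against the sample whose upper quartile is
#' closest to the mean upper quartile; log-ratios trimmed by 30% and
#' average log-abundance by 5%, precision-weighted. Factors are anchored
#' to multiply to 1 (geometric mean).
#'
#' @param counts sample x gene matrix.
#' @return numeric normalization factor per sample.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  lib <- rowSums(counts)
  uq <- apply(counts, 1, function(x) stats::quantile(x[x > 0], 0.75,
                                                     names = FALSE))
  ref <- which.min(abs(uq / lib - mean(uq / lib)))
  f <- vapply(seq_len(nrow(counts)), function(i) {
    if (i == ref) return(1)
    obs <- counts[i, ]; rf <- counts[ref, ]
    keep <- obs > 0 & rf > 0
    if (!any(keep)) return(1)
    o <- obs[keep] / lib[i]; r <- rf[keep] / lib[ref]
    M <- log2(o / r)
    A <- (log2(o) + log2(r)) / 2
    w <- (1 - o) / (obs[keep]) + (1 - r) / (rf[keep])
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (!length(M)) return(1)
    loM <- stats::quantile(M, logratio_trim, names = FALSE)
    hiM <- stats::quantile(M, 1 - logratio_trim, names = FALSE)
    loA <- stats::quantile(A, sum_trim, names = FALSE)
    hiA <- stats::quantile(A, 1 - sum_trim, names = FALSE)
    keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Cox-Reid adjusted profile NB dispersion for one gene given group-wise
# fitted means; the adjustment (-0.5 log det X'WX, block-diagonal for a
# group design) corrects the downward bias of the plain profile MLE that
# otherwise makes the LRT anti-conservative at small replicate numbers
.nb_profile_phi <- function(y, mu, group_idx) {
  nll <- function(log_phi) {
    phi <- exp(log_phi)
    w <- mu / (1 + phi * mu)
    cr <- 0.5 * sum(vapply(group_idx,
                           function(ix) log(max(sum(w[ix]), 1e-12)),
                           numeric(1)))
    -sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)) + cr
  }
  opt <- stats::optimize(nll, interval = c(log(1e-4), log(10)))
  exp(opt$minimum)
}

#' Estimate trended + tagwise NB dispersions
#'
#' Per-gene profile-likelihood dispersion given group-wise means, a lowess
#' trend of log dispersion on log mean CPM, and tagwise shrinkage toward
#' the trend (weighted in log space by `prior_df`).
#'
#' @param counts sample x gene matrix.
#' @param groups factor per sample.
#' @param eff_lib effective library sizes (lib * TMM factor).
#' @param prior_df shrinkage prior weight (default 10).
#' @return list(phi_gene, phi_trend, phi_tag).
#' @export
estimate_dispersions <- function(counts, groups, eff_lib = NULL,
                                 prior_df = 10) {
  counts <- as.matrix(counts)
  if (is.null(eff_lib)) eff_lib <- rowSums(counts) * tmm_factors(counts)
  groups <- as.factor(groups)
  n <- nrow(counts)
  group_idx <- lapply(levels(groups), function(g) which(groups == g))
  phi_gene <- vapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]
    mu <- numeric(n)
    for (idx in group_idx) {
      rate <- sum(y[idx]) / sum(eff_lib[idx])
      mu[idx] <- rate * eff_lib[idx]
    }
    if (all(mu == 0)) return(NA_real_)
    mu <- pmax(mu, 1e-8)
    .nb_profile_phi(y, mu, group_idx)
  }, numeric(1))
  mean_cpm <- colMeans(counts / eff_lib * 1e6)
  ok <- !is.na(phi_gene) & mean_cpm > 0
  if (sum(ok) >= 10) {
    lo <- stats::lowess(log(mean_cpm[ok]), log(phi_gene[ok]), f = 0.5)
    trend <- exp(stats::approx(lo$x, lo$y, xout = log(pmax(mean_cpm, 1e-8)),
                               rule = 2)$y)
  } else {
    trend <- rep(exp(mean(log(phi_gene[ok]))), ncol(counts))
  }
  df_gene <- n - nlevels(groups)
  w <- df_gene / (df_gene + prior_df)
  phi_tag <- exp(w * log(pmax(phi_gene, 1e-6)) + (1 - w) * log(trend))
  phi_tag[is.na(phi_gene)] <- trend[is.na(phi_gene)]
  list(phi_gene = phi_gene, phi_trend = trend, phi_tag = phi_tag)
}

#' Negative-binomial differential test (one vs rest)
#'
#' Per gene: NB GLM with log link, offset log effective library size, and
#' a two-level design (target group vs rest); the likelihood-ratio
#' statistic against the intercept-only model is referred to chi-squared
#' with 1 df. Fold change is reported with a pseudocount of 0.5 on the
#' group mean CPMs (reporting only; never in the likelihood).
#'
#' @param counts sample x gene matrix.
#' @param groups factor per sample.
#' @param target_group level tested against the rest.
#' @param eff_lib optional effective library sizes.
#' @param phi optional per-gene dispersions (defaults to
#'   [estimate_dispersions()] tagwise values).
#' @return data.frame (gene, log2fc, pvalue, fdr, mean_target, mean_rest,
#'   direction).
#' @export
nb_differential <- function(counts, groups, target_group, eff_lib = NULL,
                            phi = NULL) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (!target_group %in% levels(groups)) stop("unknown target group")
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  is_t <- groups == target_group
  if (sum(is_t) < 2 || sum(!is_t) < 2)
    stop("need >= 2 replicates per side for a differential test")
  if (is.null(eff_lib)) eff_lib <- rowSums(counts) * tmm_factors(counts)
  if (is.null(phi)) phi <- estimate_dispersions(counts, is_t, eff_lib)$phi_tag
  off <- log(eff_lib)
  g <- factor(ifelse(is_t, "target", "rest"), levels = c("rest", "target"))
  res <- lapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]
    cpm_t <- mean(y[is_t] / eff_lib[is_t]) * 1e6
    cpm_r <- mean(y[!is_t] / eff_lib[!is_t]) * 1e6
    lfc <- log2((cpm_t + 0.5) / (cpm_r + 0.5))
    if (all(y == 0)) {
      return(data.frame(gene = j, log2fc = 0, pvalue = 1,
                        mean_target = cpm_t, mean_rest = cpm_r))
    }
    fam <- MASS::negative.binomial(theta = 1 / max(phi[j], 1e-6))
    fit1 <- suppressWarnings(stats::glm(y ~ 1 + offset(off), family = fam))
    fit2 <- suppressWarnings(stats::glm(y ~ g + offset(off), family = fam))
    stat <- max(fit1$deviance - fit2$deviance, 0)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    data.frame(gene = j, log2fc = lfc, pvalue = p,
               mean_target = cpm_t, mean_rest = cpm_r)
  })
  out <- do.call(rbind, res)
  if (!is.null(colnames(counts))) out$gene <- colnames(counts)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out$direction <- ifelse(out$fdr >= 0.05, "ns",
                          ifelse(out$log2fc < 0, "loss", "gain"))
  out[, c("gene", "log2fc", "pvalue", "fdr", "mean_target", "mean_rest",
          "direction")]
}

#' Select cell-type-specific demethylated genes
#'
#' @param results data.frame from [nb_differential()], optionally with a
#'   `celltype` column when several contrasts are stacked.
#' @param lfc_max log2 fold-change cutoff (default -1, strict less-than).
#' @param fdr_max FDR cutoff (default 0.05, strict less-than).
#' @return subset of `results` passing both cuts.
#' @export
select_demethylated <- function(results, lfc_max = -1, fdr_max = 0.05) {
  results[!is.na(results$fdr) & results$fdr < fdr_max &
            results$log2fc < lfc_max, , drop = FALSE]
}
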