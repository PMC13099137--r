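# TF activity scores and activator/repressor classification.
#
# Motif-level activity on H3K4me1 peaks: per motif, the observed counts on
# its peak set are compared with the expectation from sample depth times
# peak popularity; the raw deviation is bias-corrected into a z-score
# against background peak sets matched on mean peak accessibility
# (a simplified form of the chromVAR procedure; synthetic data carries no
# sequence, so GC matching is not applicable). Per-TF lasso models then
# predict the motif deviation from TF expression, the TF's own gene-body
# chromatin, pseudotime and lineage; permutation of the response gives a
# significance level, and the signs of the selected coefficients classify
# each TF as activator/repressor and regulated/independent.

#' Build motif -> peak sets restricted to mark-unique peaks
#'
#' Only peaks uniquely enriched for the active mark (not co-enriched with
#' the repressive mark) are used. Motifs hitting fewer than `min_peaks`
#' unique peaks are dropped.
#'
#' @param peaks interval data.frame of H3K4me1 peaks (row order defines
#'   peak indices).
#' @param motif_hits data.frame (motif_id, chrom, start, end[, tf_id]).
#' @param unique_mask logical per peak: TRUE when the peak is
#'   H3K4me1-unique (e.g. from [partition_marks()]); NULL keeps all peaks.
#' @param min_peaks minimum peak-set size (default 10).
#' @return named list: motif_id -> integer vector of peak indices.
#' @export
build_motif_peak_sets <- function(peaks, motif_hits, unique_mask = NULL,
                                  min_peaks = 10) {
  if (is.null(unique_mask)) unique_mask <- rep(TRUE, nrow(peaks))
  pg <- intervals_to_granges(peaks)
  hg <- intervals_to_granges(motif_hits)
  ov <- GenomicRanges::findOverlaps(hg, pg, ignore.strand = TRUE)
  hit_peak <- S4Vectors::subjectHits(ov)
  hit_motif <- motif_hits$motif_id[S4Vectors::queryHits(ov)]
  keep <- unique_mask[hit_peak]
  sets <- split(hit_peak[keep], hit_motif[keep])
  sets <- lapply(sets, function(p) sort(unique(p)))
  sizes <- lengths(sets)
  dropped <- names(sets)[sizes < min_peaks]
  if (length(dropped))
    message(sprintf("dropped %d motifs with < %d unique peaks",
                    length(dropped), min_peaks))
  sets[sizes >= min_peaks]
}

#' Bias-corrected motif deviation scores
#'
#' For motif set S: expected counts per sample are
#' depth_i * sum(popularity_j, j in S) with popularity the peak's share of
#' total counts; raw deviation d_i = (obs_i - exp_i)/exp_i. `n_bg`
#' background sets of the same size, sampled (seeded) from accessibility
#' bins matched to the foreground, yield z_i = (d_i - mean(d_bg_i)) /
#' sd(d_bg_i).
#'
#' @param counts sample x peak count matrix (samples are cells or
#'   metacells).
#' @param sets named list of peak-index vectors from
#'   [build_motif_peak_sets()].
#' @param n_bg number of background sets (default 50).
#' @param n_bins accessibility bins for background matching (default 25).
#' @param seed RNG seed.
#' @return sample x motif matrix of z-scores (NA when the background
#'   deviations are degenerate, i.e. sd numerically 0).
#' @export
motif_deviation_scores <- function(counts, sets, n_bg = 50, n_bins = 25,
                                   seed = 1) {
  counts <- as.matrix(counts)
  depth <- rowSums(counts)
  pop <- colSums(counts) / sum(counts)
  force(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bins <- cut(rank(pop, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  by_bin <- split(seq_along(pop), bins)
  dev_of <- function(idx) {
    e <- depth * sum(pop[idx])
    (rowSums(counts[, idx, drop = FALSE]) - e) / pmax(e, 1e-12)
  }
  out <- matrix(NA_real_, nrow(counts), length(sets),
                dimnames = list(rownames(counts), names(sets)))
  for (m in seq_along(sets)) {
    idx <- sets[[m]]
    d <- dev_of(idx)
    fg_bins <- bins[idx]
    bg <- vapply(seq_len(n_bg), function(b) {
      samp <- vapply(fg_bins, function(bb) {
        pool <- by_bin[[bb]]
        pool[sample.int(length(pool), 1)]
      }, integer(1))
      dev_of(samp)
    }, numeric(nrow(counts)))
    mu <- rowMeans(bg)
    sdv <- apply(bg, 1, stats::sd)
    z <- (d - mu) / sdv
    z[sdv < 1e-8] <- NA_real_
    out[, m] <- z
  }
  out
}

#' Fit one TF's lasso activity model
#'
#' 70/30 train/test split (seeded); features standardized on the training
#' split only; lambda chosen by `cv_folds`-fold cross-validation on the
#' training set over a log grid (one-SE rule: the largest lambda within one
#' SE of the CV minimum); R^2 evaluated on the held-out 30%.
#'
#' @param features data.frame/matrix of per-metacell predictors
#'   (e.g. rna, k4_self, k27_self, pseudotime, lineage one-hots).
#' @param response per-metacell motif deviation vector.
#' @param split_seed seed for split and CV fold assignment.
#' @param cv_folds CV folds (default 10).
#' @param train_frac training fraction (default 0.7).
#' @return list of class `tf_model` (lambda, coefficients, r2_test,
#'   train_idx, skipped).
#' @export
fit_tf_model <- function(features, response, split_seed = 1, cv_folds = 10,
                         train_frac = 0.7) {
  X <- as.matrix(features)
  y <- as.numeric(response)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n < 30) stop("need >= 30 metacells")
  if (stats::sd(y) == 0)
    return(structure(list(lambda = NA_real_, coefficients = NULL,
                          r2_test = NA_real_, skipped = TRUE),
                     class = "tf_model"))
  force(split_seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed)
  train <- sort(sample.int(n, round(train_frac * n)))
  test <- setdiff(seq_len(n), train)
  mu <- colMeans(X[train, , drop = FALSE])
  sdev <- apply(X[train, , drop = FALSE], 2, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  foldid <- sample(rep_len(seq_len(cv_folds), length(train)))
  Xtr <- Xs[train, , drop = FALSE]; ytr <- y[train]
  full <- glmnet::glmnet(Xtr, ytr, alpha = 1, nlambda = 30,
                         standardize = FALSE)
  lambda_seq <- full$lambda
  # manual 10-fold CV over the shared lambda path (one-SE rule)
  cverr <- matrix(NA_real_, cv_folds, length(lambda_seq))
  for (f in seq_len(cv_folds)) {
    inb <- foldid != f
    gf <- glmnet::glmnet(Xtr[inb, , drop = FALSE], ytr[inb], alpha = 1,
                         lambda = lambda_seq, standardize = FALSE)
    pr <- Xtr[!inb, , drop = FALSE] %*% as.matrix(gf$beta)
    pr <- sweep(pr, 2, gf$a0, "+")
    k <- ncol(pr)  # may be < length(lambda_seq) if the path stopped early
    cverr[f, seq_len(k)] <- colMeans((ytr[!inb] - pr[, seq_len(k),
                                                     drop = FALSE])^2)
  }
  ok_lam <- colSums(is.na(cverr)) == 0
  cverr <- cverr[, ok_lam, drop = FALSE]
  lambda_seq <- lambda_seq[ok_lam]
  cvm <- colMeans(cverr)
  cvse <- apply(cverr, 2, stats::sd) / sqrt(cv_folds)
  best <- which.min(cvm)
  lam_idx <- min(which(cvm <= cvm[best] + cvse[best]))
  lam <- lambda_seq[lam_idx]
  idx_full <- match(lam, full$lambda)
  beta <- as.matrix(full$beta)[, idx_full]
  a0 <- full$a0[idx_full]
  pred <- as.numeric(Xs[test, , drop = FALSE] %*% beta + a0)
  r2 <- 1 - sum((y[test] - pred)^2) / sum((y[test] - mean(y[test]))^2)
  coefs <- as.numeric(beta)
  names(coefs) <- colnames(X)
  structure(list(lambda = lam, coefficients = coefs, r2_test = r2,
                 train_idx = train, skipped = FALSE),
            class = "tf_model")
}

#' Permutation significance for TF models
#'
#' Re-runs the full split/CV protocol on permuted responses;
#' p = (1 + #{R^2_perm >= R^2_obs}) / (1 + n_perm), BH-adjusted across
#' TFs. TFs with padj below `padj_max` are selected for classification.
#'
#' @param results named list of `tf_model` objects (one per TF).
#' @param responses sample x TF matrix of deviations (columns matched to
#'   `results` by name).
#' @param features the predictor table used for the observed fits (per TF:
#'   a list matched by name, or a single shared data.frame).
#' @param n_perm number of permutations (default 200). Note the joint
#'   resolution bound: the smallest achievable BH-adjusted p is
#'   (1/(n_perm+1)) * n_tf / n_signif, so with few motifs a small `n_perm`
#'   makes selection at `padj_max` unattainable; < 19 warns.
#' @param seed RNG seed.
#' @param cv_folds passed through to [fit_tf_model()].
#' @return data.frame (tf_id, r2_test, perm_pvalue, padj, selected).
#' @export
permutation_significance <- function(results, responses, features,
                                     n_perm = 200, seed = 1, cv_folds = 10,
                                     padj_max = 0.01) {
  if (n_perm < 19)
    warning("n_perm < 19: p-value resolution too coarse for alpha = 0.05")
  shared_features <- !is.list(features) || is.data.frame(features)
  force(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pvals <- vapply(names(results), function(tf) {
    obs <- results[[tf]]
    if (isTRUE(obs$skipped) || is.na(obs$r2_test)) return(NA_real_)
    feat <- if (shared_features) features else features[[tf]]
    y <- responses[, tf]
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      yp <- sample(y)
      fit <- fit_tf_model(feat, yp, split_seed = seed + b,
                          cv_folds = cv_folds)
      if (!is.na(fit$r2_test) && fit$r2_test >= obs$r2_test)
        exceed <- exceed + 1L
    }
    (1 + exceed) / (1 + n_perm)
  }, numeric(1))
  padj <- stats::p.adjust(pvals, method = "BH")
  data.frame(tf_id = names(results),
             r2_test = vapply(results, function(r) r$r2_test, numeric(1)),
             perm_pvalue = pvals, padj = padj,
             selected = !is.na(padj) & padj < padj_max,
             row.names = NULL)
}

#' Classify a selected TF from its lasso coefficients
#'
#' Activity class by the sign of the TF-expression (`rna`) coefficient
#' (zero -> unclassified); regulation class is "regulated" when the TF's
#' own gene-body chromatin (`k4_self` or `k27_self`) carries nonzero
#' weight, else "independent". Unselected TFs get NA classes.
#'
#' @param model `tf_model`.
#' @param selected was the TF selected (padj < 0.01)?
#' @return list(activity_class, regulation_class).
#' @export
classify_tf <- function(model, selected = TRUE) {
  if (!selected || isTRUE(model$skipped))
    return(list(activity_class = NA_character_,
                regulation_class = NA_character_))
  co <- model$coefficients
  rna <- if ("rna" %in% names(co)) co[["rna"]] else 0
  k4 <- if ("k4_self" %in% names(co)) co[["k4_self"]] else 0
  k27 <- if ("k27_self" %in% names(co)) co[["k27_self"]] else 0
  activity <- if (rna > 0) "activator" else if (rna < 0) "repressor" else
    "unclassified"
  regulation <- if (k4 != 0 || k27 != 0) "regulated" else "independent"
  list(activity_class = activity, regulation_class = regulation)
}

#' Full TF program analysis
#'
#' Fits all TF models, computes permutation significance, and classifies
#' the selected TFs.
#'
#' @param features shared predictor data.frame minus the TF-specific
#'   columns; per-TF columns `rna`, `k4_self`, `k27_self` are taken from
#'   the matching lists.
#' @param deviations sample x motif deviation matrix (one column per TF).
#' @param tf_features named list: tf_id -> data.frame with columns rna,
#'   k4_self, k27_self (per sample).
#' @param n_perm,seed,cv_folds,padj_max see [permutation_significance()].
#' @param r2_min additional reporting cut on test R^2 (default 0.6);
#'   recorded as `high_accuracy`, not used for selection.
#' @return data.frame, one row per TF, with coefficients, significance and
#'   classes.
#' @export
tf_program_analysis <- function(features, deviations, tf_features,
                                n_perm = 200, seed = 1, cv_folds = 10,
                                padj_max = 0.01, r2_min = 0.6) {
  tfs <- colnames(deviations)
  feats <- lapply(tfs, function(tf) cbind(tf_features[[tf]], features))
  names(feats) <- tfs
  models <- lapply(tfs, function(tf)
    fit_tf_model(feats[[tf]], deviations[, tf], split_seed = seed,
                 cv_folds = cv_folds))
  names(models) <- tfs
  sig <- permutation_significance(models, deviations, feats,
                                  n_perm = n_perm, seed = seed,
                                  cv_folds = cv_folds, padj_max = padj_max)
  cls <- lapply(tfs, function(tf)
    classify_tf(models[[tf]],
                selected = sig$selected[sig$tf_id == tf]))
  co <- do.call(rbind, lapply(models, function(m) {
    if (isTRUE(m$skipped)) return(c(rna = NA_real_, k4_self = NA_real_,
                                    k27_self = NA_real_))
    m$coefficients[c("rna", "k4_self", "k27_self")]
  }))
  out <- cbind(sig, coef_rna = co[, "rna"], coef_k4_self = co[, "k4_self"],
               coef_k27_self = co[, "k27_self"],
               activity_class = vapply(cls, `[[`, character(1),
                                       "activity_class"),
               regulation_class = vapply(cls, `[[`, character(1),
                                         "regulation_class"))
  out$high_accuracy <- !is.na(out$r2_test) & out$r2_test > r2_min
  rownames(out) <- NULL
  out
}
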