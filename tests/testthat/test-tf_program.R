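test_that("motif peak sets respect uniqueness and size filters", {
  peaks <- data.frame(chrom = "c1", start = seq(0, 11000, 1000),
                      end = seq(500, 11500, 1000), strand = ".")
  # motif A hits peaks 1-12, motif B hits peaks 1-3 only
  hits <- data.frame(
    motif_id = c(rep("A", 12), rep("B", 3)),
    chrom = "c1",
    start = c(seq(100, 11100, 1000), seq(100, 2100, 1000)),
    end = c(seq(200, 11200, 1000), seq(200, 2200, 1000)))
  sets <- suppressMessages(build_motif_peak_sets(peaks, hits,
                                                 min_peaks = 10))
  expect_named(sets, "A")
  expect_equal(sets$A, 1:12)

  # a hit inside a co-enriched peak is excluded from the motif's set
  uniq <- rep(TRUE, 12); uniq[1] <- FALSE
  sets2 <- suppressMessages(build_motif_peak_sets(peaks, hits, uniq,
                                                  min_peaks = 10))
  expect_equal(sets2$A, 2:12)

  # two motifs sharing peaks both carry the shared peak
  hits3 <- rbind(hits, data.frame(motif_id = "C", chrom = "c1",
                                  start = seq(100, 11100, 1000),
                                  end = seq(200, 11200, 1000)))
  sets3 <- suppressMessages(build_motif_peak_sets(peaks, hits3,
                                                  min_peaks = 10))
  expect_true(1 %in% sets3$A && 1 %in% sets3$C)
})

test_that("deviation scores are zero under the expectation identity", {
  # counts exactly proportional to depth x popularity
  depth <- c(1, 2, 4, 8)
  pop <- c(5, 1, 2, 2, 10, 3, 7, 1, 4, 6)
  counts <- outer(depth, pop)
  sets <- list(m1 = c(1, 3, 5), m2 = c(2, 8))
  z <- motif_deviation_scores(counts, sets, n_bg = 10, n_bins = 3, seed = 1)
  # raw deviations of foreground and every background set are all zero, so
  # the z-score is 0/0 -> NA; check via the raw deviation directly
  e <- rowSums(counts) * sum(pop[c(1, 3, 5)]) / sum(pop)
  expect_equal(unname(rowSums(counts[, c(1, 3, 5)])), unname(e),
               tolerance = 1e-12)
  expect_true(all(is.na(z[, "m1"])))
})

test_that("planted motif signal yields positive deviations where planted", {
  set.seed(2)
  n_mc <- 60; n_pk <- 200
  base <- matrix(rpois(n_mc * n_pk, 20), n_mc, n_pk)
  idx <- 1:15
  on <- 1:30  # first half of metacells carry 2x signal on the motif peaks
  base[on, idx] <- base[on, idx] + matrix(rpois(30 * 15, 20), 30, 15)
  z <- motif_deviation_scores(base, list(m = idx), n_bg = 50, seed = 3)
  expect_gt(mean(z[on, "m"]), mean(z[-on, "m"]))
  # sign test: planted metacells overwhelmingly positive
  expect_lt(binom.test(sum(z[on, "m"] > 0), 30, 0.5,
                       alternative = "greater")$p.value, 0.01)

  # scale invariance: multiplying all counts by a scalar leaves z unchanged
  z2 <- motif_deviation_scores(base * 3, list(m = idx), n_bg = 50, seed = 3)
  expect_equal(z2, z, tolerance = 1e-10)

  # null construction: signal-free matrix gives near-zero mean z
  z0 <- motif_deviation_scores(matrix(rpois(n_mc * n_pk, 20), n_mc, n_pk),
                               list(m = idx), n_bg = 50, seed = 4)
  expect_lt(abs(mean(z0)), 0.8)
})

test_that("lasso model recovers a constructed linear signal", {
  set.seed(5)
  n <- 120
  feats <- data.frame(rna = rnorm(n), k4_self = rnorm(n),
                      k27_self = rnorm(n), pseudotime = runif(n))
  y <- 2 * feats$rna + rnorm(n, 0, 0.05)
  fit <- fit_tf_model(feats, y, split_seed = 1)
  expect_gt(fit$coefficients[["rna"]], 0)
  expect_lt(max(abs(fit$coefficients[c("k4_self", "k27_self")])), 0.05)
  expect_gt(fit$r2_test, 0.95)

  # pure-noise response: r2_test near zero
  r2s <- vapply(1:30, function(s) {
    fit_tf_model(feats, rnorm(n), split_seed = s)$r2_test
  }, numeric(1))
  expect_gte(mean(r2s <= 0.1), 0.9)

  # lasso limit: at the largest grid lambda all coefficients vanish
  g <- glmnet::glmnet(as.matrix(feats), y, alpha = 1, nlambda = 30)
  expect_true(all(abs(g$beta[, 1]) < 1e-12))

  # constant response is skipped
  expect_true(fit_tf_model(feats, rep(1, n), split_seed = 1)$skipped)
})

test_that("permutation p-values follow the add-one bound and BH is exact", {
  d <- simulate_tf_metacells(n_metacells = 100, n_act = 2, n_rep = 1,
                             n_null = 1, noise_sd = 0.2, seed = 7)
  feats <- lapply(names(d$tf_features), function(tf)
    cbind(d$tf_features[[tf]], d$shared))
  names(feats) <- names(d$tf_features)
  models <- lapply(names(feats), function(tf)
    fit_tf_model(feats[[tf]], d$responses[, tf], split_seed = 1))
  names(models) <- names(feats)
  expect_warning(
    sig <- permutation_significance(models, d$responses, feats,
                                    n_perm = 15, seed = 2),
    "n_perm")
  # strong TFs beat all permutations: p = 1/(n_perm+1)
  expect_equal(min(sig$perm_pvalue), 1 / 16)
  # BH equals the hand rule applied to these p-values
  expect_equal(sig$padj, p.adjust(sig$perm_pvalue, "BH"))
  expect_true(all(sig$padj >= sig$perm_pvalue))
})

test_that("TF classification follows the coefficient sign rules", {
  mk <- function(co) structure(list(coefficients = co, skipped = FALSE),
                               class = "tf_model")
  c1 <- classify_tf(mk(c(rna = 0.4, k4_self = 0, k27_self = 0)))
  expect_equal(c1$activity_class, "activator")
  expect_equal(c1$regulation_class, "independent")

  c2 <- classify_tf(mk(c(rna = -0.3, k4_self = 0, k27_self = -0.2)))
  expect_equal(c2$activity_class, "repressor")
  expect_equal(c2$regulation_class, "regulated")

  c3 <- classify_tf(mk(c(rna = 0, k4_self = 0.5, k27_self = 0)))
  expect_equal(c3$activity_class, "unclassified")
  expect_equal(c3$regulation_class, "regulated")

  # unselected TF: classes absent
  c4 <- classify_tf(mk(c(rna = 1, k4_self = 0, k27_self = 0)),
                    selected = FALSE)
  expect_true(is.na(c4$activity_class))
})

test_that("planted TF programs are classified correctly end to end", {
  d <- simulate_tf_metacells(n_metacells = 120, n_act = 4, n_rep = 4,
                             n_null = 2, seed = 11)
  out <- tf_program_analysis(d$shared, d$responses, d$tf_features,
                             n_perm = 60, seed = 3, padj_max = 0.05)
  m <- merge(out, d$truth, by = "tf_id")
  planted <- m[m$activity != "null", ]
  sel <- planted[planted$selected, ]
  expect_gte(nrow(sel), 6)
  expect_gte(mean(sel$activity_class == sel$activity), 0.8)
  # nulls have low r2 and are not selected
  expect_true(all(!m$selected[m$activity == "null"]))
  # regulated TFs carry self-chromatin weight
  reg <- m[!is.na(m$regulation) & m$regulation == "regulated" & m$selected, ]
  if (nrow(reg) >= 2)
    expect_gte(mean(reg$regulation_class == "regulated"), 0.5)
})
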