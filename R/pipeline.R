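# End-to-end orchestration on synthetic (or pre-loaded) paired data:
# QC -> normalization -> ChIC LSA embedding -> metacells -> domain calling
# -> spreading/silencing/coupling -> TF program -> differential chromatin.
# Every stochastic stage takes a seed derived from the global seed by
# hashing the stage name, so one config + seed reproduces identical
# outputs.

#' Pipeline configuration
#'
#' Unknown arguments are rejected. Defaults are the study conditions of
#' the synthetic analyses.
#'
#' @param sim `sim_config` for the synthetic dataset.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param nc number of metacells.
#' @param min_per_mark minimum cells of each mark per metacell.
#' @param n_pcs transcriptome PCA dimensions for metacell assignment.
#' @param n_hvg highly variable genes for the embedding.
#' @param chic_min_cuts,chic_max_cuts ChIC QC bounds.
#' @param rna_min_total,rna_max_genes,rna_max_top100,rna_min_coding RNA QC
#'   thresholds.
#' @param lsa `lsa_params` for the ChIC embedding.
#' @param domain `domain_params` for the domain caller.
#' @param spreading_frac center-bin detection fraction.
#' @param r_threshold spreading-flag correlation cutoff.
#' @param n_perm TF permutation count.
#' @param tf_padj_max TF selection threshold.
#' @param diff_min_metacells minimum metacells per cell type.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1, nc = 60,
                            min_per_mark = 20, n_pcs = 20, n_hvg = 300,
                            chic_min_cuts = 30, chic_max_cuts = 100000,
                            rna_min_total = 1000, rna_max_genes = 10000,
                            rna_max_top100 = 0.6, rna_min_coding = 0.70,
                            lsa = lsa_params(), domain = domain_params(
                              bin_size = sim$bin_size),
                            spreading_frac = 0.05, r_threshold = 0.3,
                            n_perm = 200, tf_padj_max = 0.01,
                            diff_min_metacells = 3) {
  structure(as.list(environment()), class = "pipeline_config")
}

# deterministic per-stage seed below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (seed * 10007 + h) %% 2147483647L
}

#' Sum chic bin counts over feature intervals per metacell
#'
#' @param mc_bins metacell x bin matrix (columns in genome order).
#' @param first_bin,last_bin 1-based inclusive bin ranges per feature.
#' @return metacell x feature matrix.
#' @export
counts_over_bins <- function(mc_bins, first_bin, last_bin) {
  out <- vapply(seq_along(first_bin), function(i) {
    rowSums(mc_bins[, first_bin[i]:last_bin[i], drop = FALSE])
  }, numeric(nrow(mc_bins)))
  matrix(out, nrow = nrow(mc_bins))
}

#' Run the full pipeline
#'
#' @param config `pipeline_config`.
#' @param dataset optional pre-generated dataset (defaults to
#'   [simulate_dataset()] with `config$sim`).
#' @param out_dir optional directory; result tables are written as TSV.
#' @param stages character vector of stages to run (dependency order is
#'   enforced; later stages need the earlier ones).
#' @return list with per-stage results and a `manifest` data.frame.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         out_dir = NULL,
                         stages = c("qc", "embed", "metacells", "domains",
                                    "spreading", "silencing", "coupling",
                                    "tf", "differential")) {
  if (is.null(dataset)) dataset <- simulate_dataset(config$sim)
  res <- list(config = config)
  genes <- dataset$gene_models
  bs <- config$sim$bin_size

  # ---- QC ----
  mask27 <- filter_cells_chic(dataset$chic_k27, config$chic_min_cuts,
                              config$chic_max_cuts)
  mask4 <- filter_cells_chic(dataset$chic_k4, config$chic_min_cuts,
                             config$chic_max_cuts)
  rna_mask <- filter_cells_rna(dataset$rna_spliced, genes,
                               min_total = config$rna_min_total,
                               max_genes = config$rna_max_genes,
                               max_top100_frac = config$rna_max_top100,
                               min_coding_frac = config$rna_min_coding)
  bc27 <- dataset$chic_k27$cell_meta$barcode[mask27]
  bc4 <- dataset$chic_k4$cell_meta$barcode[mask4]
  keep_bc <- intersect(dataset$rna_spliced$cell_meta$barcode[rna_mask],
                       c(bc27, bc4))
  k27 <- subset_cells(dataset$chic_k27,
                      dataset$chic_k27$cell_meta$barcode %in% keep_bc)
  k4 <- subset_cells(dataset$chic_k4,
                     dataset$chic_k4$cell_meta$barcode %in% keep_bc)
  rna_s <- subset_cells(dataset$rna_spliced,
                        dataset$rna_spliced$cell_meta$barcode %in% keep_bc)
  rna_u <- subset_cells(dataset$rna_unspliced,
                        dataset$rna_unspliced$cell_meta$barcode %in% keep_bc)
  res$qc <- data.frame(stage = "qc", n_k27 = nrow(k27$counts),
                       n_k4 = nrow(k4$counts), n_cells = nrow(rna_s$counts))
  if (!any(c("embed", "metacells", "domains", "spreading", "silencing",
             "coupling", "tf", "differential") %in% stages))
    return(res)

  # ---- transcriptome embedding (for metacells) + ChIC LSA ----
  keep_genes <- filter_genes_presence(rna_s)
  hvg <- hvg_pearson_residuals(subset_cells(rna_s, features = keep_genes),
                               norm_params(n_hvg = config$n_hvg))
  pr <- pearson_residual_matrix(rna_s, hvg$feature_id)
  pca <- stats::prcomp(pr, rank. = config$n_pcs, center = TRUE,
                       scale. = FALSE)
  rna_embedding <- pca$x
  res$embedding <- rna_embedding
  if ("embed" %in% stages) {
    res$lsa <- tryCatch(embed_chic(k27, config$lsa),
                        error = function(e) NULL)
  }

  # ---- metacells ----
  ms <- assign_metacells(rna_embedding, config$nc,
                         seed = stage_seed(config$seed, "metacells"))
  marks <- rna_s$cell_meta$mark
  ms <- balance_marks(ms, marks, min_cells = config$min_per_mark,
                      seed = stage_seed(config$seed, "balance"))
  ms <- annotate_metacells(ms, rna_s$cell_meta$cell_type,
                           rna_s$cell_meta$latent_time,
                           rna_s$cell_meta$timepoint_hpf)
  res$metacells <- ms
  is27 <- marks == "H3K27me3"
  bc_all <- rna_s$cell_meta$barcode
  idx27 <- match(k27$cell_meta$barcode, bc_all)
  idx4 <- match(k4$cell_meta$barcode, bc_all)
  mc_k27 <- aggregate_counts(k27, ms, cells = idx27)
  mc_k4 <- aggregate_counts(k4, ms, cells = idx4)
  mc_spl <- aggregate_counts(rna_s, ms)
  mc_uns <- aggregate_counts(rna_u, ms)
  keep_mc <- which(ms$annotations$n_cells > 0)
  ann <- ms$annotations[keep_mc, ]
  mc_k27 <- mc_k27[keep_mc, , drop = FALSE]
  mc_k4 <- mc_k4[keep_mc, , drop = FALSE]
  mc_spl <- mc_spl[keep_mc, , drop = FALSE]
  mc_uns <- mc_uns[keep_mc, , drop = FALSE]
  mc_lineage <- sub("_(pluri|mid|late)$", "", ann$label)
  res$metacell_annotations <- ann
  if (!any(c("domains", "spreading", "silencing", "coupling", "tf",
             "differential") %in% stages))
    return(res)

  # ---- domains on pooled pseudobulk ----
  track27 <- Matrix::colSums(k27$counts)
  track4 <- Matrix::colSums(k4$counts)
  dom27 <- call_domains(track27, config$domain, chrom = "chr1")
  dom27 <- refine_subpeaks(dom27, track27, config$domain)
  dom4 <- call_domains(track4, config$domain, chrom = "chr1")
  dom4 <- refine_subpeaks(dom4, track4, config$domain)
  dom27 <- annotate_domains(dom27, genes)
  dom4 <- annotate_domains(dom4, genes)
  part <- partition_marks(dom27, dom4, labels = c("H3K27me3", "H3K4me1"))
  res$domains_k27 <- dom27
  res$domains_k4 <- dom4
  res$mark_partition <- part

  # ---- spreading ----
  if ("spreading" %in% stages && nrow(mc_k27) >= 10) {
    pluri <- k27$cell_meta$lineage == "pluripotent"
    centers <- find_center_bins(k27, pluri, config$spreading_frac)
    res$centers <- centers
    if (length(centers)) {
      res$spreading <- spreading_scan(mc_k27, centers,
                                      lineages = factor(mc_lineage),
                                      r_threshold = config$r_threshold)
    }
  }

  # ---- silencing ----
  if ("silencing" %in% stages && nrow(dom27)) {
    dgr <- intervals_to_granges(dom27)
    ggr <- intervals_to_granges(genes)
    ov <- GenomicRanges::findOverlaps(ggr, dgr, ignore.strand = TRUE)
    hits <- S4Vectors::queryHits(ov)
    doms <- S4Vectors::subjectHits(ov)
    # one domain per gene: the largest-overlap domain
    ow <- GenomicRanges::width(IRanges::pintersect(ggr[hits], dgr[doms],
                                                   ignore.strand = TRUE))
    o <- order(hits, -ow)
    first <- !duplicated(hits[o])
    gi <- hits[o][first]; di <- doms[o][first]
    sil <- do.call(rbind, lapply(seq_along(gi), function(k) {
      g <- gi[k]; d <- di[k]
      fb <- floor(dom27$start[d] / bs) + 1L
      lb <- ceiling(dom27$end[d] / bs)
      k27_mc <- rowSums(mc_k27[, fb:lb, drop = FALSE])
      uns_mc <- mc_uns[, genes$gene_id[g]]
      fit <- silencing_fit(uns_mc, k27_mc, genes$intron_length_bp[g],
                           dom27$end[d] - dom27$start[d])
      cbind(gene_id = genes$gene_id[g], fit)
    }))
    res$silencing <- sil
  }

  # ---- coupling ----
  if ("coupling" %in% stages) {
    gb_k4 <- counts_over_bins(mc_k4, genes$first_bin, genes$last_bin)
    colnames(gb_k4) <- genes$gene_id
    ok_mc <- rowSums(gb_k4) > 0 & rowSums(mc_spl) > 0
    nm_k4 <- as.matrix(shifted_log(round(gb_k4[ok_mc, , drop = FALSE])))
    nm_rna <- as.matrix(shifted_log(mc_spl[ok_mc, genes$gene_id,
                                           drop = FALSE]))
    res$coupling <- coupling_correlation(nm_k4, nm_rna,
                                         ann$mean_latent_time[ok_mc])
  }

  # ---- TF program ----
  if ("tf" %in% stages && nrow(mc_k4) >= 30) {
    k4_peaks <- dom4[part$partition[part$set == "H3K4me1"] == "H3K4me1_unique",
                     , drop = FALSE]
    if (nrow(k4_peaks) >= 3) {
      sets <- build_motif_peak_sets(k4_peaks, dataset$motif_hits,
                                    min_peaks = 5)
      if (length(sets)) {
        pk_fb <- floor(k4_peaks$start / bs) + 1L
        pk_lb <- ceiling(k4_peaks$end / bs)
        mc_peak <- counts_over_bins(mc_k4, pk_fb, pk_lb)
        dev <- motif_deviation_scores(mc_peak, sets,
                                      seed = stage_seed(config$seed, "tf"))
        tf_ids <- sub("^M_", "", colnames(dev))
        gb_k4 <- counts_over_bins(mc_k4, genes$first_bin, genes$last_bin)
        gb_k27 <- counts_over_bins(mc_k27, genes$first_bin, genes$last_bin)
        colnames(gb_k4) <- colnames(gb_k27) <- genes$gene_id
        nm_spl <- as.matrix(shifted_log(mc_spl))
        nm_gb4 <- log1p(gb_k4); nm_gb27 <- log1p(gb_k27)
        tf_feats <- lapply(tf_ids, function(tf) {
          data.frame(rna = nm_spl[, tf], k4_self = nm_gb4[, tf],
                     k27_self = nm_gb27[, tf])
        })
        names(tf_feats) <- colnames(dev)
        lin_f <- factor(mc_lineage)
        shared <- data.frame(pseudotime = ann$mean_latent_time,
                             stats::model.matrix(~ lin_f - 1))
        res$tf <- tf_program_analysis(shared, dev, tf_feats,
                                      n_perm = config$n_perm,
                                      seed = stage_seed(config$seed, "tfperm"),
                                      padj_max = config$tf_padj_max)
        res$tf$tf_id <- sub("^M_", "", res$tf$tf_id)
      }
    }
  }

  # ---- differential ----
  if ("differential" %in% stages) {
    gb_k27 <- counts_over_bins(mc_k27, genes$first_bin, genes$last_bin)
    colnames(gb_k27) <- genes$gene_id
    cts <- filter_celltypes(ann$label, config$diff_min_metacells)
    late <- grep("_late$", cts, value = TRUE)
    diffs <- list()
    for (ct in late) {
      groups <- factor(ifelse(ann$label == ct, ct, "rest"))
      keepg <- filter_by_expression(gb_k27, groups)
      if (!sum(keepg)) next
      d <- nb_differential(gb_k27[, keepg, drop = FALSE], groups, ct)
      d$celltype <- ct
      diffs[[ct]] <- d
    }
    if (length(diffs)) {
      res$differential <- do.call(rbind, diffs)
      rownames(res$differential) <- NULL
      res$demethylated <- select_demethylated(res$differential)
    }
  }

  res$manifest <- data.frame(
    stage = stages,
    seed = vapply(stages, function(s) stage_seed(config$seed, s),
                  numeric(1)),
    row.names = NULL)
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' Write pipeline result tables as TSV
#'
#' @param res output of [run_pipeline()].
#' @param out_dir directory (created).
#' @return invisibly, the written paths.
#' @export
write_pipeline_results <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, name) {
    if (is.null(obj)) return()
    p <- file.path(out_dir, paste0(name, ".tsv"))
    data.table::fwrite(as.data.frame(obj), p, sep = "\t")
    paths <<- c(paths, p)
  }
  wr(res$qc, "qc_summary")
  wr(res$metacell_annotations, "metacell_annotations")
  wr(res$domains_k27, "domains_H3K27me3")
  wr(res$domains_k4, "domains_H3K4me1")
  wr(res$mark_partition, "mark_partition")
  wr(res$spreading, "spreading")
  wr(res$silencing, "silencing")
  wr(res$coupling, "coupling")
  wr(res$tf, "tf_classification")
  wr(res$differential, "differential")
  wr(res$demethylated, "demethylated_genes")
  wr(res$manifest, "manifest")
  invisible(paths)
}
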