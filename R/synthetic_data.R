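# Synthetic paired ChIC + RNA single-cell datasets with planted ground
# truth. The generator emulates the statistical structure the downstream
# models assume: negative-binomial bin counts with lognormal cell-depth
# variation, pseudotime-ordered cells branching into lineages, center bins
# whose flanking signal grows with the realized center signal
# (cis-spreading), genes whose unspliced output decays as a power of the
# H3K27me3 density on their domain, and TF programs whose motif-peak
# H3K4me1 signal tracks TF expression positively (activator), negatively
# (repressor), or not at all (null), optionally read out through the TF's
# own gene-body chromatin (regulated).
#
# Metacell-level simulators for single stages (spreading, silencing,
# TF models, domain tracks) generate data directly at the scale the
# corresponding model consumes; the full simulate_dataset() exercises the
# whole pipeline end to end.

#' Simulation configuration
#'
#' Defaults are the study conditions every recovery test runs under.
#'
#' @param n_cells_per_mark cells per histone mark (each cell carries one
#'   mark plus RNA).
#' @param n_lineages lineages after the branch point.
#' @param n_bins,bin_size genome size: `n_bins` bins of `bin_size` bp on
#'   one contig.
#' @param n_genes total genes.
#' @param depth_meanlog,depth_sdlog lognormal per-cell depth factors.
#' @param nb_dispersion NB dispersion phi (variance mu + phi*mu^2).
#' @param n_spreading_loci planted cis-spreading centers.
#' @param spreading_slope true beta1 of the neighbor-on-center regression.
#' @param n_silenced_genes genes silenced by H3K27me3 density.
#' @param silencing_slope true slope of log2 unspliced density on log2
#'   H3K27me3 density.
#' @param n_tfs total TFs; split into activators/repressors/nulls by
#'   `tf_split` (half the non-null TFs are chromatin-regulated).
#' @param tf_split integer c(activator, repressor, null), summing to n_tfs.
#' @param n_peaks H3K4me1 peaks.
#' @param branch_time latent time of the lineage branch point.
#' @param maternal_rna emulate maternal transcripts (spliced high early,
#'   unspliced rising later).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_mark = 2000, n_lineages = 3,
                       n_bins = 5000, bin_size = 5000, n_genes = 800,
                       depth_meanlog = 0, depth_sdlog = 0.35,
                       nb_dispersion = 0.3, n_spreading_loci = 40,
                       spreading_slope = 0.8, n_silenced_genes = 60,
                       silencing_slope = -1, n_tfs = 20,
                       tf_split = c(8, 8, 4), n_peaks = 500,
                       branch_time = 0.3, maternal_rna = TRUE, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_cells_per_mark > 0, n_lineages > 0, n_bins > 0, n_genes > 0,
            nb_dispersion > 0, sum(tf_split) == n_tfs)
  # bin budget: spreading windows, silenced domains, peaks, gene slots
  need <- n_spreading_loci * 25 + n_silenced_genes * 6 + n_peaks * 2 +
    n_tfs * 3 + (n_genes - n_silenced_genes - n_tfs) * 2
  if (need > n_bins)
    stop(sprintf("infeasible config: %d bins needed, %d available",
                 need, n_bins))
  structure(cfg, class = "sim_config")
}

.rnb <- function(n, mu, phi) {
  stats::rnbinom(n, size = 1 / phi, mu = mu)
}

# smooth sigmoidal ramp from 0 to 1 centered at m with width w
.ramp <- function(t, m, w = 0.08) 1 / (1 + exp(-(t - m) / w))

#' Simulate a full paired-modality dataset
#'
#' @param config `sim_config`.
#' @return list with cell_matrix entries `chic_k27`, `chic_k4`,
#'   `rna_spliced`, `rna_unspliced`, plus `gene_models`, `motif_hits`,
#'   `chrom_sizes`, `bins`, and `truth` (planted ground truth).
#' @export
simulate_dataset <- function(config = sim_config()) {
  force(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  nb <- config$n_bins
  phi <- config$nb_dispersion
  n_mark <- config$n_cells_per_mark
  n_cells <- 2L * n_mark
  lineage_names <- paste0("L", seq_len(config$n_lineages))

  # ---- cells ----
  t_lat <- stats::runif(n_cells)
  lineage <- ifelse(t_lat < config$branch_time, "pluripotent",
                    sample(lineage_names, n_cells, replace = TRUE))
  maturity <- ifelse(t_lat < config$branch_time, "pluri",
                     ifelse(t_lat < 0.65, "mid", "late"))
  cell_type <- ifelse(lineage == "pluripotent", "pluripotent",
                      paste0(lineage, "_", maturity))
  hpf_levels <- c(4, 6, 8, 10, 12, 24)
  timepoint <- hpf_levels[cut(t_lat, breaks = seq(0, 1, length.out = 7),
                              include.lowest = TRUE, labels = FALSE)]
  mark <- rep(c("H3K27me3", "H3K4me1"), each = n_mark)
  cell_meta <- data.frame(
    barcode = sprintf("cell%05d", seq_len(n_cells)),
    timepoint_hpf = timepoint, batch = "b1", mark = mark,
    lineage = lineage, cell_type = cell_type, latent_time = t_lat)

  # ---- genome layout ----
  bins <- bin_genome(data.frame(chrom = "chr1",
                                length = nb * config$bin_size),
                     config$bin_size)
  cursor <- 1L
  take <- function(n) {
    idx <- cursor:(cursor + n - 1L)
    cursor <<- cursor + n
    idx
  }
  # spreading loci: 25-bin blocks, center at offset 13
  sp_centers <- integer(0)
  for (i in seq_len(config$n_spreading_loci)) {
    blk <- take(25L)
    sp_centers <- c(sp_centers, blk[13])
  }
  # silenced-gene domains: 6-bin blocks, domain = middle 4 bins
  sil_domains <- lapply(seq_len(config$n_silenced_genes), function(i) {
    blk <- take(6L)
    blk[2:5]
  })
  # H3K4me1 peaks: 2-bin blocks, peak = first bin
  pk_bins <- vapply(seq_len(config$n_peaks), function(i) take(2L)[1],
                    integer(1))
  # TF gene bodies: 3-bin blocks, body = first 2 bins
  tf_body <- lapply(seq_len(config$n_tfs), function(i) take(3L)[1:2])
  # other genes: 2-bin blocks, body = first bin
  n_other <- config$n_genes - config$n_silenced_genes - config$n_tfs
  other_bins <- vapply(seq_len(n_other), function(i) take(2L)[1], integer(1))

  # ---- TF programs ----
  n_act <- config$tf_split[1]; n_rep <- config$tf_split[2]
  n_null <- config$tf_split[3]
  tf_ids <- sprintf("tf%02d", seq_len(config$n_tfs))
  tf_activity <- rep(c("activator", "repressor", "null"),
                     times = c(n_act, n_rep, n_null))
  tf_regulated <- rep(FALSE, config$n_tfs)
  planted <- which(tf_activity != "null")
  tf_regulated[planted[seq_len(floor(length(planted) / 2))]] <- TRUE
  tf_sign <- ifelse(tf_activity == "activator", 1,
                    ifelse(tf_activity == "repressor", -1, 0))
  zstd <- function(v) (v - mean(v)) / stats::sd(v)
  ramp_mid <- stats::runif(config$n_tfs, 0.25, 0.7)
  tf_lineage <- sample(c(lineage_names, "all"), config$n_tfs, replace = TRUE)
  phase <- stats::runif(config$n_tfs)
  expr_prog <- sapply(seq_len(config$n_tfs), function(f) {
    lin_ok <- tf_lineage[f] == "all" | lineage == tf_lineage[f] |
      lineage == "pluripotent"
    1 + 4 * .ramp(t_lat, ramp_mid[f]) * lin_ok
  })
  hidden_prog <- sapply(seq_len(config$n_tfs), function(f) {
    sin(2 * pi * (1.5 * t_lat + phase[f]))
  })
  tf_act <- sapply(seq_len(config$n_tfs), function(f) {
    if (tf_activity[f] == "null") return(zstd(stats::rnorm(n_cells)))
    ze <- zstd(expr_prog[, f])
    if (tf_regulated[f]) 0.6 * tf_sign[f] * ze + 0.8 * zstd(hidden_prog[, f])
    else tf_sign[f] * ze
  })

  # ---- depths ----
  d_chic <- stats::rlnorm(n_cells, config$depth_meanlog, config$depth_sdlog)
  d_rna <- stats::rlnorm(n_cells, config$depth_meanlog, config$depth_sdlog)

  # ---- H3K27me3 counts (cells of mark 1) ----
  # Background is sparse (pre-marked regions are a small minority of the
  # genome); most H3K27me3 is gained during development, either on planted
  # spreading loci/silenced-gene domains or as de-novo gain on gene bodies.
  k27_cells <- which(mark == "H3K27me3")
  nk <- length(k27_cells)
  base27 <- stats::rgamma(nb, shape = 2, rate = 2 / 0.01)
  m27 <- matrix(.rnb(nk * nb, rep(d_chic[k27_cells], nb) *
                       rep(base27, each = nk), phi), nk, nb)
  tk <- t_lat[k27_cells]
  lin_k <- lineage[k27_cells]
  late_k <- maturity[k27_cells] == "late"
  # centers: signal growing with latent time, detectable in pluripotent cells
  for (cb in sp_centers) {
    mu_c <- d_chic[k27_cells] * (0.5 + 8 * tk)
    xc <- .rnb(nk, mu_c, phi)
    m27[, cb] <- m27[, cb] + xc
    nb_idx <- setdiff((cb - 10):(cb + 10), cb)
    # flanking rate conditional on the realized center signal: the window
    # sum then follows E[Y|X] = const + beta1 * X at any aggregation level
    extra <- config$spreading_slope * xc / length(nb_idx)
    for (jb in nb_idx)
      m27[, jb] <- m27[, jb] + stats::rpois(nk, extra)
  }
  # silenced-gene domains: density rising 2^(3t)
  dens_rel <- 2^(3 * tk)
  for (db in sil_domains) {
    mu_d <- d_chic[k27_cells] * 0.15 * dens_rel
    for (jb in db) m27[, jb] <- m27[, jb] + .rnb(nk, mu_d, phi)
  }
  # de novo H3K27me3 gain on "other" gene bodies with development; a
  # subset is demethylated (lost) late in one designated lineage, which is
  # the planted truth for the differential stage
  n_demeth <- min(30L, n_other)
  demeth_lin <- rep(lineage_names, length.out = n_demeth)
  for (i in seq_len(n_other)) {
    mu_g <- d_chic[k27_cells] * 0.35 * .ramp(tk, 0.55)
    if (i <= n_demeth) {
      lost <- late_k & lin_k == demeth_lin[i]
      mu_g[lost] <- mu_g[lost] * 0.25
    }
    m27[, other_bins[i]] <- m27[, other_bins[i]] + .rnb(nk, mu_g, phi)
  }

  # ---- H3K4me1 counts (cells of mark 2) ----
  k4_cells <- which(mark == "H3K4me1")
  n4 <- length(k4_cells)
  base4 <- stats::rgamma(nb, shape = 2, rate = 2 / 0.01)
  m4 <- matrix(.rnb(n4 * nb, rep(d_chic[k4_cells], nb) *
                      rep(base4, each = n4), phi), n4, nb)
  # peaks: baseline elevation everywhere; TF-owned peaks modulated by the
  # TF's activity program
  pk_rate <- stats::rlnorm(config$n_peaks, log(0.8), 0.3)
  n_owned <- min(config$n_tfs * 20L, config$n_peaks)
  owner <- c(rep(seq_len(config$n_tfs), length.out = n_owned),
             rep(NA_integer_, config$n_peaks - n_owned))
  act4 <- tf_act[k4_cells, , drop = FALSE]
  for (p in seq_len(config$n_peaks)) {
    mult <- if (is.na(owner[p])) rep(1, n4) else
      exp(0.7 * act4[, owner[p]])
    m4[, pk_bins[p]] <- m4[, pk_bins[p]] +
      .rnb(n4, d_chic[k4_cells] * pk_rate[p] * mult, phi)
  }
  # some peaks also gain H3K27me3 late (co-enriched; excluded by the
  # unique-peak filter downstream)
  co_pk <- seq_len(max(1, round(0.15 * config$n_peaks)))
  for (p in co_pk) {
    m27[, pk_bins[p]] <- m27[, pk_bins[p]] +
      .rnb(nk, d_chic[k27_cells] * 0.3 * dens_rel, phi)
  }
  # TF gene bodies: chromatin-regulated TFs carry their hidden program on
  # their own gene-body H3K4me1
  h4 <- hidden_prog[k4_cells, , drop = FALSE]
  for (f in seq_len(config$n_tfs)) {
    mult <- if (tf_regulated[f]) exp(1.2 * zstd(h4[, f])) else rep(1, n4)
    for (jb in tf_body[[f]])
      m4[, jb] <- m4[, jb] + .rnb(n4, d_chic[k4_cells] * 0.4 * mult, phi)
  }

  # ---- gene models ----
  bs <- config$bin_size
  sil_ids <- sprintf("sil%03d", seq_len(config$n_silenced_genes))
  oth_ids <- sprintf("g%04d", seq_len(n_other))
  gene_tab <- rbind(
    data.frame(gene_id = sil_ids,
               first_bin = vapply(sil_domains, min, integer(1)),
               last_bin = vapply(sil_domains, max, integer(1)),
               role = "silenced"),
    data.frame(gene_id = tf_ids,
               first_bin = vapply(tf_body, min, integer(1)),
               last_bin = vapply(tf_body, max, integer(1)), role = "tf"),
    data.frame(gene_id = oth_ids, first_bin = other_bins,
               last_bin = other_bins, role = "other"))
  strand <- sample(c("+", "-"), nrow(gene_tab), replace = TRUE)
  gstart <- (gene_tab$first_bin - 1L) * bs
  gend <- gene_tab$last_bin * bs
  genes <- gene_models(
    gene_id = gene_tab$gene_id, chrom = "chr1", start = gstart, end = gend,
    strand = strand, tss = ifelse(strand == "+", gstart, gend - 1L),
    intron_length_bp = pmax(round(stats::runif(nrow(gene_tab), 1000, 5000)),
                            1L))
  genes$role <- gene_tab$role
  genes$first_bin <- gene_tab$first_bin
  genes$last_bin <- gene_tab$last_bin

  # ---- RNA counts ----
  ng <- nrow(genes)
  base_expr <- stats::rlnorm(ng, log(2), 0.5)
  names(base_expr) <- genes$gene_id
  spl_rate <- matrix(rep(base_expr, each = n_cells), n_cells, ng)
  uns_rate <- 0.3 * spl_rate
  colnames(spl_rate) <- colnames(uns_rate) <- genes$gene_id
  # lineage markers among the "other" genes drive the embedding structure
  n_marker <- min(40 * config$n_lineages, n_other)
  marker_ids <- oth_ids[seq_len(n_marker)]
  marker_lin <- rep(lineage_names, length.out = n_marker)
  for (i in seq_len(n_marker)) {
    on <- 1 + 6 * .ramp(t_lat, 0.4) * (lineage == marker_lin[i])
    spl_rate[, marker_ids[i]] <- spl_rate[, marker_ids[i]] * on
    uns_rate[, marker_ids[i]] <- uns_rate[, marker_ids[i]] * on
  }
  # maternal transcripts: spliced high early, unspliced rising later
  if (config$maternal_rna && n_other > n_marker) {
    mat_ids <- oth_ids[(n_marker + 1):min(n_marker + 60, n_other)]
    for (gid in mat_ids) {
      spl_rate[, gid] <- spl_rate[, gid] * 4 * 2^(-3 * t_lat)
      uns_rate[, gid] <- uns_rate[, gid] * (0.2 + 2 * .ramp(t_lat, 0.5))
    }
  }
  # silenced genes: unspliced density decays as a power of K27 density
  for (i in seq_len(config$n_silenced_genes)) {
    gid <- sil_ids[i]
    rel <- 2^(3 * t_lat)  # same density trajectory planted in chic
    uns_rate[, gid] <- 3 * rel^config$silencing_slope *
      genes$intron_length_bp[match(gid, genes$gene_id)] / 3000
    spl_rate[, gid] <- base_expr[gid] * 2^(config$silencing_slope *
                                             3 * pmax(t_lat - 0.15, 0))
  }
  # TF genes: expression follows the TF's program
  for (f in seq_len(config$n_tfs)) {
    spl_rate[, tf_ids[f]] <- 1.5 * expr_prog[, f]
    uns_rate[, tf_ids[f]] <- 0.5 * expr_prog[, f]
  }
  spl <- matrix(.rnb(n_cells * ng, as.vector(spl_rate) *
                       rep(d_rna, ng), phi), n_cells, ng)
  uns <- matrix(.rnb(n_cells * ng, as.vector(uns_rate) *
                       rep(d_rna, ng), phi), n_cells, ng)

  # ---- assemble ----
  feat_bins <- data.frame(feature_id = bins$bin_id, chrom = bins$chrom,
                          start = bins$start, end = bins$end)
  feat_genes <- data.frame(feature_id = genes$gene_id, chrom = genes$chrom,
                           start = genes$start, end = genes$end)
  peaks <- data.frame(chrom = "chr1", start = (pk_bins - 1L) * bs,
                      end = pk_bins * bs, strand = ".",
                      peak_id = sprintf("pk%04d", seq_len(config$n_peaks)),
                      bin = pk_bins)
  motif_hits <- data.frame(
    motif_id = paste0("M_", tf_ids[owner[!is.na(owner)]]),
    chrom = "chr1",
    start = (pk_bins[!is.na(owner)] - 1L) * bs + round(bs / 2) - 50L,
    end = (pk_bins[!is.na(owner)] - 1L) * bs + round(bs / 2) + 50L,
    score = round(stats::runif(sum(!is.na(owner)), 5, 15), 2),
    tf_id = tf_ids[owner[!is.na(owner)]])
  truth <- list(
    spreading_centers = data.frame(bin = sp_centers,
                                   beta1_true = rep(config$spreading_slope,
                                                    length(sp_centers))),
    silenced_genes = data.frame(gene_id = sil_ids,
                                slope_true = rep(config$silencing_slope,
                                                 length(sil_ids)),
                                domain_first_bin = vapply(sil_domains, min,
                                                          integer(1)),
                                domain_last_bin = vapply(sil_domains, max,
                                                         integer(1))),
    tf_classes = data.frame(tf_id = tf_ids, activity = tf_activity,
                            regulation = ifelse(tf_activity == "null", NA,
                                                ifelse(tf_regulated,
                                                       "regulated",
                                                       "independent"))),
    peak_owner = data.frame(peak_id = peaks$peak_id,
                            tf_id = ifelse(is.na(owner), NA,
                                           tf_ids[owner])),
    co_enriched_peaks = peaks$peak_id[co_pk],
    demethylated_genes = data.frame(gene_id = oth_ids[seq_len(n_demeth)],
                                    lineage = demeth_lin),
    seed = config$seed)
  list(
    chic_k27 = cell_matrix(m27, "chic", "H3K27me3",
                           cell_meta[k27_cells, ], feat_bins),
    chic_k4 = cell_matrix(m4, "chic", "H3K4me1",
                          cell_meta[k4_cells, ], feat_bins),
    rna_spliced = cell_matrix(spl, "rna_spliced", NULL, cell_meta,
                              feat_genes),
    rna_unspliced = cell_matrix(uns, "rna_unspliced", NULL, cell_meta,
                                feat_genes),
    gene_models = genes, motif_hits = motif_hits, peaks = peaks,
    chrom_sizes = data.frame(chrom = "chr1",
                             length = nb * config$bin_size),
    bins = bins, truth = truth, config = config)
}

#' Write a simulated dataset to an MTX/BED/TSV directory
#'
#' @param dataset output of [simulate_dataset()].
#' @param out_dir directory (created).
#' @return manifest data.frame (file, kind) also written as manifest.tsv;
#'   the manifest records the generator seed.
#' @export
write_dataset <- function(dataset, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  for (nm in c("chic_k27", "chic_k4", "rna_spliced", "rna_unspliced")) {
    p <- write_cell_matrix(dataset[[nm]], out_dir, nm)
    files <- c(files, p)
  }
  gm_path <- file.path(out_dir, "gene_models.tsv")
  data.table::fwrite(dataset$gene_models, gm_path, sep = "\t")
  mh_path <- file.path(out_dir, "motif_hits.tsv")
  data.table::fwrite(dataset$motif_hits, mh_path, sep = "\t")
  cs_path <- file.path(out_dir, "chrom_sizes.tsv")
  data.table::fwrite(dataset$chrom_sizes, cs_path, sep = "\t")
  tr_path <- file.path(out_dir, "truth_silenced_genes.tsv")
  data.table::fwrite(dataset$truth$silenced_genes, tr_path, sep = "\t")
  sp_path <- file.path(out_dir, "truth_spreading_centers.tsv")
  data.table::fwrite(dataset$truth$spreading_centers, sp_path, sep = "\t")
  tf_path <- file.path(out_dir, "truth_tf_classes.tsv")
  data.table::fwrite(dataset$truth$tf_classes, tf_path, sep = "\t")
  files <- c(files, gm_path, mh_path, cs_path, tr_path, sp_path, tf_path)
  manifest <- data.frame(file = basename(files),
                         kind = "data", seed = dataset$config$seed)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t")
  manifest
}

# ---- stage-level simulators ------------------------------------------------

#' Metacell-level cis-spreading simulation
#'
#' Center signal X per metacell follows an NB around a pseudotime-rising
#' mean; neighbor signal Y = beta0 + beta1 * X + Gaussian noise with
#' standard deviation sd(beta1 * X) / snr.
#'
#' @param n_metacells metacells.
#' @param beta1 true slope.
#' @param snr signal-to-noise ratio (signal sd over noise sd).
#' @param beta0 intercept.
#' @param n_lineages lineage levels (for the LRT; no lineage effect is
#'   planted unless `lineage_effect` is nonzero).
#' @param lineage_effect additive per-lineage shift on Y (default 0: null).
#' @param seed RNG seed.
#' @return data.frame (x, y, lineage, latent_time).
#' @export
simulate_spreading_metacells <- function(n_metacells = 150, beta1 = 0.8,
                                         snr = 3, beta0 = 5,
                                         n_lineages = 3,
                                         lineage_effect = 0, seed = 1) {
  force(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t_m <- stats::runif(n_metacells)
  x <- .rnb(n_metacells, 20 + 200 * t_m, 0.3)
  sig <- stats::sd(beta1 * x)
  lin <- factor(sample(paste0("L", seq_len(n_lineages)), n_metacells,
                       replace = TRUE))
  y <- beta0 + beta1 * x + lineage_effect * (as.integer(lin) - 1) +
    stats::rnorm(n_metacells, 0, sig / snr)
  data.frame(x = x, y = y, lineage = lin, latent_time = t_m)
}

#' Metacell-level gene-silencing simulation
#'
#' H3K27me3 density rises 2^(3 t) along pseudotime; unspliced counts scale
#' as density^slope. Counts are NB with the configured dispersion.
#'
#' @param n_metacells,n_genes dimensions.
#' @param slope true silencing slope.
#' @param phi NB dispersion.
#' @param cells_per_metacell pooled cells per metacell (scales counts).
#' @param seed RNG seed.
#' @return list: `k27` and `unspliced` (metacell x gene count matrices),
#'   `intron_length_bp`, `domain_length_bp`, `latent_time`.
#' @export
simulate_silencing_metacells <- function(n_metacells = 100, n_genes = 100,
                                         slope = -1, phi = 0.3,
                                         cells_per_metacell = 20, seed = 1) {
  force(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t_m <- sort(stats::runif(n_metacells))
  rel <- 2^(3 * t_m)
  domain_len <- round(stats::runif(n_genes, 10000, 30000))
  intron_len <- round(stats::runif(n_genes, 1000, 5000))
  k27 <- sapply(seq_len(n_genes), function(g) {
    mu <- cells_per_metacell * 0.5 * rel * domain_len[g] / 10000
    .rnb(n_metacells, mu, phi / cells_per_metacell)
  })
  unspliced <- sapply(seq_len(n_genes), function(g) {
    mu <- cells_per_metacell * 3 * rel^slope * intron_len[g] / 3000
    .rnb(n_metacells, mu, phi / cells_per_metacell)
  })
  list(k27 = k27, unspliced = unspliced, intron_length_bp = intron_len,
       domain_length_bp = domain_len, latent_time = t_m)
}

#' Metacell-level TF-model simulation
#'
#' Generates per-metacell features (rna, k4_self, k27_self, pseudotime,
#' lineage one-hots) and motif-deviation responses for planted activators
#' (response tracks rna positively), repressors (negatively), regulated
#' TFs (response partly carried by the TF's own gene-body chromatin) and
#' nulls (pure noise).
#'
#' @param n_metacells metacells.
#' @param n_act,n_rep,n_null TF counts by class.
#' @param frac_regulated fraction of planted TFs that are
#'   chromatin-regulated.
#' @param noise_sd residual noise sd on the response (signal is
#'   standardized).
#' @param seed RNG seed.
#' @return list: `responses` (metacell x TF), `tf_features` (per-TF
#'   data.frames), `shared` (pseudotime + lineage one-hots), `truth`.
#' @export
simulate_tf_metacells <- function(n_metacells = 120, n_act = 8, n_rep = 8,
                                  n_null = 4, frac_regulated = 0.5,
                                  noise_sd = 0.35, seed = 1) {
  force(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_tf <- n_act + n_rep + n_null
  tf_ids <- sprintf("tf%02d", seq_len(n_tf))
  activity <- rep(c("activator", "repressor", "null"),
                  times = c(n_act, n_rep, n_null))
  sgn <- ifelse(activity == "activator", 1,
                ifelse(activity == "repressor", -1, 0))
  planted <- which(activity != "null")
  regulated <- rep(FALSE, n_tf)
  regulated[sample(planted, round(frac_regulated * length(planted)))] <- TRUE
  t_m <- stats::runif(n_metacells)
  lin <- factor(sample(paste0("L", 1:3), n_metacells, replace = TRUE))
  lin_oh <- stats::model.matrix(~ lin - 1)
  zstd <- function(v) (v - mean(v)) / stats::sd(v)
  responses <- matrix(0, n_metacells, n_tf, dimnames = list(NULL, tf_ids))
  tf_features <- vector("list", n_tf)
  names(tf_features) <- tf_ids
  for (f in seq_len(n_tf)) {
    e <- zstd(1 + 4 * .ramp(t_m, stats::runif(1, 0.25, 0.7)) +
                0.1 * stats::rnorm(n_metacells))
    h <- zstd(sin(2 * pi * (1.5 * t_m + stats::runif(1))) +
                0.1 * stats::rnorm(n_metacells))
    rna <- e + 0.15 * stats::rnorm(n_metacells)
    k4_self <- if (regulated[f]) h + 0.15 * stats::rnorm(n_metacells) else
      stats::rnorm(n_metacells)
    k27_self <- stats::rnorm(n_metacells)
    signal <- if (activity[f] == "null") rep(0, n_metacells) else
      if (regulated[f]) 0.6 * sgn[f] * e + 0.8 * h else sgn[f] * e
    responses[, f] <- signal + stats::rnorm(n_metacells,
                                            0, if (activity[f] == "null") 1
                                            else noise_sd)
    tf_features[[f]] <- data.frame(rna = rna, k4_self = k4_self,
                                   k27_self = k27_self)
  }
  shared <- data.frame(pseudotime = t_m, lin_oh)
  list(responses = responses, tf_features = tf_features, shared = shared,
       truth = data.frame(tf_id = tf_ids, activity = activity,
                          regulation = ifelse(activity == "null", NA,
                                              ifelse(regulated, "regulated",
                                                     "independent"))))
}

#' Simulate a binned pseudo-bulk track with planted enriched domains
#'
#' Poisson background with `n_plants` planted regions of `plant_bins`
#' consecutive bins at `fold` times the background rate.
#'
#' @param n_bins track length in bins.
#' @param background background mean per bin.
#' @param n_plants,plant_bins,fold plant geometry and enrichment.
#' @param min_gap_bins minimum spacing between plant starts.
#' @param seed RNG seed.
#' @return list: `counts` (integer vector), `plants` (data.frame
#'   first_bin, last_bin).
#' @export
simulate_domain_track <- function(n_bins = 50000, background = 2,
                                  n_plants = 100, plant_bins = 20,
                                  fold = 10, min_gap_bins = 100, seed = 1) {
  force(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (n_plants * (plant_bins + min_gap_bins) > n_bins)
    stop("infeasible: plants do not fit the track")
  counts <- stats::rpois(n_bins, background)
  slots <- floor(n_bins / (plant_bins + min_gap_bins))
  starts <- (sample(slots, n_plants) - 1) * (plant_bins + min_gap_bins) +
    sample(min_gap_bins %/% 2, n_plants, replace = TRUE) + 1
  plants <- data.frame(first_bin = as.integer(starts),
                       last_bin = as.integer(starts + plant_bins - 1))
  for (i in seq_len(n_plants)) {
    idx <- plants$first_bin[i]:plants$last_bin[i]
    counts[idx] <- stats::rpois(length(idx), background * fold)
  }
  list(counts = counts, plants = plants)
}
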