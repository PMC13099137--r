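# Broad-domain calling on pooled pseudo-bulk bin counts.
#
# A two-state (background / enriched) hidden Markov model with
# negative-binomial emissions is fitted by EM and posterior-decoded;
# maximal runs of enriched bins become domains, and domains whose mean
# enriched-state posterior falls below `posterior_min` are removed.
# Sharper "subpeaks" inside domains are scored MACS-style
# (-10*log10 Poisson p against a local lambda from the surrounding 10 kb)
# and replace their parent domain when any reaches `enrichment_min`.
# Domains are then classified against gene models (promoter > gene_covering
# > genic > intergenic) and two marks' domain sets are partitioned into
# unique / co-enriched regions.

#' Domain-caller parameters
#'
#' @param bin_size bp per bin of the input track (default 750).
#' @param posterior_min minimum mean enriched-state posterior (default 0.4).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return list of class `domain_params`.
#' @export
domain_params <- function(bin_size = 750, posterior_min = 0.4,
                          max_iter = 200, tol = 1e-6) {
  structure(list(bin_size = bin_size, posterior_min = posterior_min,
                 max_iter = max_iter, tol = tol), class = "domain_params")
}

# forward-backward for a 2-state HMM in log space (scaled); compiled kernel
.hmm_forward_backward <- function(logem, trans, init) {
  hmm_forward_backward_cpp(logem, trans, init)
}

# weighted method-of-moments NB fit: mean mu, dispersion phi (var = mu+phi*mu^2)
.nb_wfit <- function(x, w) {
  mu <- sum(w * x) / sum(w)
  v <- sum(w * (x - mu)^2) / sum(w)
  phi <- max((v - mu) / mu^2, 1e-4)
  c(mu = max(mu, 1e-6), phi = phi)
}

#' Call enriched domains on a binned count track
#'
#' @param binned_counts non-negative integer vector, one value per bin of a
#'   single chromosome/contig.
#' @param params `domain_params`.
#' @param chrom chromosome name used in the output intervals.
#' @return data.frame of domains (chrom, start, end, strand,
#'   mean_posterior, source, first_bin, last_bin), non-overlapping and
#'   sorted; zero rows if nothing is enriched.
#' @export
call_domains <- function(binned_counts, params = domain_params(),
                         chrom = "chr1") {
  x <- as.numeric(binned_counts)
  if (any(x < 0)) stop("counts must be non-negative")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mean_posterior = numeric(0), source = character(0),
                      first_bin = integer(0), last_bin = integer(0))
  if (all(x == 0) || stats::sd(x) == 0) return(empty)
  # init: background at median, enriched at the 95th percentile
  mu <- c(max(stats::quantile(x, 0.5), 0.1),
          max(stats::quantile(x, 0.95), 0.2))
  if (mu[2] <= mu[1]) mu[2] <- mu[1] * 2 + 1
  phi <- c(0.1, 0.1)
  trans <- matrix(c(0.99, 0.01, 0.05, 0.95), 2, 2, byrow = TRUE)
  init <- c(0.9, 0.1)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    logem <- cbind(stats::dnbinom(x, size = 1 / phi[1], mu = mu[1], log = TRUE),
                   stats::dnbinom(x, size = 1 / phi[2], mu = mu[2], log = TRUE))
    fb <- .hmm_forward_backward(logem, trans, init)
    g <- fb$gamma
    f1 <- .nb_wfit(x, g[, 1]); f2 <- .nb_wfit(x, g[, 2])
    # keep state identity: state 2 is the high-mean state
    if (f2["mu"] < f1["mu"]) { tmp <- f1; f1 <- f2; f2 <- tmp; g <- g[, 2:1] }
    mu <- c(f1["mu"], f2["mu"]); phi <- c(f1["phi"], f2["phi"])
    rs <- rowSums(fb$xi)
    trans <- fb$xi / ifelse(rs > 0, rs, 1)
    trans <- pmax(trans, 1e-6); trans <- trans / rowSums(trans)
    init <- pmax(g[1, ], 1e-6); init <- init / sum(init)
    if (abs(fb$loglik - ll_old) < params$tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- fb$loglik
  }
  if (!converged && params$max_iter > 1)
    warning("EM did not converge; using last iterate")
  logem <- cbind(stats::dnbinom(x, size = 1 / phi[1], mu = mu[1], log = TRUE),
                 stats::dnbinom(x, size = 1 / phi[2], mu = mu[2], log = TRUE))
  post <- .hmm_forward_backward(logem, trans, init)$gamma[, 2]
  enriched <- post > 0.5
  if (!any(enriched)) return(empty)
  r <- rle(enriched)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  out <- lapply(runs, function(k) {
    i <- starts[k]; j <- ends[k]
    data.frame(chrom = chrom,
               start = as.integer((i - 1) * params$bin_size),
               end = as.integer(j * params$bin_size),
               strand = ".",
               mean_posterior = mean(post[i:j]),
               source = "domain", first_bin = i, last_bin = j)
  })
  out <- do.call(rbind, out)
  out <- out[out$mean_posterior >= params$posterior_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score and detect subpeaks, replacing parents by the merge rule
#'
#' Candidate segments are maximal runs of bins above the parent domain's
#' mean; each segment is scored -10*log10 of the Poisson upper-tail
#' probability of its summed counts against lambda estimated from the
#' surrounding 10 kb (domain plus flanks). Segments reaching
#' `enrichment_min` become subpeaks; any domain containing at least one
#' subpeak is replaced by its subpeaks, others pass through unchanged.
#'
#' @param domains output of [call_domains()].
#' @param binned_counts the same track the domains were called on.
#' @param params `domain_params`.
#' @param enrichment_min minimum local enrichment score (default 50).
#' @param flank_bp width of the local background window (default 10000).
#' @return data.frame of domains and subpeaks (same columns, plus
#'   `enrichment_score`).
#' @export
refine_subpeaks <- function(domains, binned_counts, params = domain_params(),
                            enrichment_min = 50, flank_bp = 10000) {
  x <- as.numeric(binned_counts)
  bs <- params$bin_size
  flank_bins <- max(1L, round(flank_bp / bs))
  pieces <- lapply(seq_len(nrow(domains)), function(di) {
    d <- domains[di, ]
    i <- d$first_bin; j <- d$last_bin
    seg_vals <- x[i:j]
    lo <- max(1, i - flank_bins); hi <- min(length(x), j + flank_bins)
    # local background: the larger of the 10-kb window mean and the
    # domain's own mean, so a subpeak must stand out above its parent
    lambda <- max(mean(x[lo:hi]), mean(seg_vals), 1e-6)
    above <- seg_vals > mean(seg_vals)
    d$enrichment_score <- NA_real_
    if (!any(above)) return(d)
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    subs <- lapply(which(r$values), function(k) {
      a <- starts[k]; b <- ends[k]
      tot <- sum(seg_vals[a:b]); len <- b - a + 1
      p <- stats::ppois(tot - 1, lambda * len, lower.tail = FALSE)
      score <- -10 * log10(max(p, 1e-300))
      data.frame(chrom = d$chrom,
                 start = as.integer((i + a - 2) * bs),
                 end = as.integer((i + b - 1) * bs),
                 strand = ".", mean_posterior = d$mean_posterior,
                 source = "subpeak", first_bin = i + a - 1,
                 last_bin = i + b - 1, enrichment_score = score)
    })
    subs <- do.call(rbind, subs)
    subs <- subs[subs$enrichment_score >= enrichment_min, , drop = FALSE]
    if (nrow(subs)) subs else d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Apply the domain/subpeak merge rule to precomputed calls
#'
#' Domains containing at least one subpeak (by interval containment) are
#' replaced by those subpeaks; domains without subpeaks pass through.
#'
#' @param domains,subpeaks interval data.frames.
#' @return combined interval data.frame with a `source` column.
#' @export
merge_subpeaks <- function(domains, subpeaks) {
  if (is.null(subpeaks) || nrow(subpeaks) == 0) {
    domains$source <- "domain"
    return(domains)
  }
  dg <- intervals_to_granges(domains)
  sg <- intervals_to_granges(subpeaks)
  ov <- GenomicRanges::findOverlaps(sg, dg, type = "within")
  has_sub <- seq_len(nrow(domains)) %in% S4Vectors::subjectHits(ov)
  keep_dom <- domains[!has_sub, , drop = FALSE]
  keep_sub <- subpeaks[S4Vectors::queryHits(ov), , drop = FALSE]
  if (nrow(keep_dom)) keep_dom$source <- "domain"
  if (nrow(keep_sub)) keep_sub$source <- "subpeak"
  common <- intersect(names(keep_dom), names(keep_sub))
  out <- rbind(keep_dom[, common, drop = FALSE],
               keep_sub[, common, drop = FALSE])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify domains against gene models
#'
#' Class priority: promoter > gene_covering > genic > intergenic.
#' The promoter window is strand-aware: 200 bp upstream to 300 bp
#' downstream of the TSS. A domain is gene_covering when it overlaps at
#' least `cover_frac` of some gene's length. Each domain is annotated with
#' its overlapping genes, or the nearest gene when intergenic.
#'
#' @param domains interval data.frame.
#' @param genes gene model table (strand required, "+" or "-").
#' @param upstream,downstream promoter window extents in bp.
#' @param cover_frac gene-covering fraction threshold (default 0.8).
#' @return domains with `class` and `genes` (comma-joined ids) columns.
#' @export
annotate_domains <- function(domains, genes, upstream = 200,
                             downstream = 300, cover_frac = 0.8) {
  if (nrow(domains) == 0) {
    domains$class <- character(0); domains$genes <- character(0)
    return(domains)
  }
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene models must have explicit strand for promoter annotation")
  dg <- intervals_to_granges(domains)
  gg <- intervals_to_granges(genes)
  prom_start <- ifelse(genes$strand == "+", genes$tss - upstream,
                       genes$tss - downstream + 1)
  prom_end <- ifelse(genes$strand == "+", genes$tss + downstream,
                     genes$tss + upstream)
  pg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(pmax(prom_start + 1, 1),
                                                prom_end))
  ov_p <- GenomicRanges::findOverlaps(dg, pg, ignore.strand = TRUE)
  ov_g <- GenomicRanges::findOverlaps(dg, gg, ignore.strand = TRUE)
  ovl_width <- GenomicRanges::width(IRanges::pintersect(
    dg[S4Vectors::queryHits(ov_g)], gg[S4Vectors::subjectHits(ov_g)],
    ignore.strand = TRUE))
  gene_len <- genes$end - genes$start
  covering <- ovl_width >= cover_frac * gene_len[S4Vectors::subjectHits(ov_g)]
  cls <- rep("intergenic", nrow(domains))
  cls[unique(S4Vectors::queryHits(ov_g))] <- "genic"
  cls[unique(S4Vectors::queryHits(ov_g)[covering])] <- "gene_covering"
  cls[unique(S4Vectors::queryHits(ov_p))] <- "promoter"
  gene_of <- vapply(seq_len(nrow(domains)), function(i) {
    hits <- S4Vectors::subjectHits(ov_g)[S4Vectors::queryHits(ov_g) == i]
    ph <- S4Vectors::subjectHits(ov_p)[S4Vectors::queryHits(ov_p) == i]
    hits <- union(hits, ph)
    if (length(hits)) return(paste(genes$gene_id[sort(hits)], collapse = ","))
    nearest <- GenomicRanges::nearest(dg[i], gg, ignore.strand = TRUE)
    if (is.na(nearest)) NA_character_ else genes$gene_id[nearest]
  }, character(1))
  domains$class <- cls
  domains$genes <- gene_of
  domains
}

#' Partition two marks' domain sets by overlap
#'
#' Every input domain is assigned exactly one class: co-enriched when it
#' overlaps (any bp) a domain of the other mark, otherwise unique to its
#' own mark.
#'
#' @param dom_a,dom_b interval data.frames for marks A and B.
#' @param labels names for the two marks (used in the `set` column).
#' @return data.frame of all domains with columns `set` (mark label) and
#'   `partition` in {A_unique, B_unique, co_enriched}.
#' @export
partition_marks <- function(dom_a, dom_b,
                            labels = c("A", "B")) {
  ga <- intervals_to_granges(dom_a)
  gb <- intervals_to_granges(dom_b)
  a_hit <- GenomicRanges::countOverlaps(ga, gb, ignore.strand = TRUE) > 0
  b_hit <- GenomicRanges::countOverlaps(gb, ga, ignore.strand = TRUE) > 0
  common <- intersect(names(dom_a), names(dom_b))
  out <- rbind(
    cbind(dom_a[, common, drop = FALSE], set = labels[1],
          partition = ifelse(a_hit, "co_enriched",
                             paste0(labels[1], "_unique"))),
    cbind(dom_b[, common, drop = FALSE], set = labels[2],
          partition = ifelse(b_hit, "co_enriched",
                             paste0(labels[2], "_unique"))))
  rownames(out) <- NULL
  out
}
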