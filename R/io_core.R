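#' comap: single-cell chromatin + transcriptome co-mapping analysis
#'
#' Core containers and readers live in this file: genomic intervals
#' (0-based, half-open, BED-native), the `cell_matrix` container holding a
#' sparse cells x features count matrix with aligned metadata, gene models,
#' and MatrixMarket/BED/TSV input-output.
#'
#' @importFrom Matrix readMM writeMM sparseMatrix colSums rowSums t Diagonal
#' @importFrom data.table fread fwrite data.table as.data.table :=
#' @importFrom stats rnorm runif rbinom rpois rnbinom rlnorm kmeans prcomp
#'   cor lm logLik pchisq pnorm ppois p.adjust sd var coef optimize lowess
#'   approx quantile median dnbinom predict setNames aggregate
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib comap, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# ---- genomic intervals ------------------------------------------------------

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based, half-open (BED convention) everywhere in this
#' package. `strand` may be "+", "-" or "." (unstranded).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand character vector in `c("+", "-", ".")`, recycled.
#' @return data.frame with columns chrom, start, end, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  gi <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(gi)
  gi
}

validate_intervals <- function(gi) {
  stopifnot(all(c("chrom", "start", "end") %in% names(gi)))
  if (any(gi$start < 0)) stop("interval start must be >= 0")
  if (any(gi$start >= gi$end)) stop("interval must satisfy start < end")
  if ("strand" %in% names(gi) && !all(gi$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(gi)
}

#' Convert interval table to GRanges (1-based, closed) for overlap math
#' @noRd
intervals_to_granges <- function(gi) {
  GenomicRanges::GRanges(
    seqnames = gi$chrom,
    ranges = IRanges::IRanges(start = gi$start + 1L, end = gi$end),
    strand = if ("strand" %in% names(gi)) {
      ifelse(gi$strand == ".", "*", gi$strand)
    } else "*")
}

#' Tile a genome into fixed-width bins
#'
#' Produces contiguous half-open bins covering each chromosome exactly once;
#' the last bin of a chromosome is truncated at the chromosome end.
#'
#' @param chrom_sizes data.frame with columns `chrom` and `length` (bp).
#' @param bin_size bin width in bp, > 0.
#' @return interval data.frame (strand ".") with an added `bin_id` column
#'   of the form `chrom:start-end`.
#' @export
bin_genome <- function(chrom_sizes, bin_size) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  stopifnot(all(c("chrom", "length") %in% names(chrom_sizes)))
  pieces <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    len <- chrom_sizes$length[i]
    starts <- seq.int(0L, len - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    data.frame(chrom = chrom_sizes$chrom[i], start = as.integer(starts),
               end = as.integer(ends), strand = ".",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$bin_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Read a BED file (3+ columns) into an interval table
#'
#' Coordinates are kept 0-based half-open as in the file. Column 4 (name),
#' 5 (score) and 6 (strand) are used when present.
#'
#' @param path BED file path.
#' @return interval data.frame; `name`/`score` columns included if present.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 3) stop("BED file must have >= 3 columns")
  gi <- data.frame(chrom = as.character(dt[[1]]),
                   start = as.integer(dt[[2]]),
                   end = as.integer(dt[[3]]),
                   strand = if (ncol(dt) >= 6) as.character(dt[[6]]) else ".",
                   stringsAsFactors = FALSE)
  if (ncol(dt) >= 4) gi$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) gi$score <- dt[[5]]
  validate_intervals(gi)
  gi
}

#' Write an interval table as BED
#'
#' Emits BED3 if only coordinates are present, BED6 if name/score/strand
#' are available (missing name -> ".", missing score -> 0).
#'
#' @param gi interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(gi, path) {
  validate_intervals(gi)
  has6 <- any(c("name", "score") %in% names(gi)) ||
    ("strand" %in% names(gi) && any(gi$strand != "."))
  if (has6) {
    out <- data.frame(gi$chrom, gi$start, gi$end,
                      if ("name" %in% names(gi)) gi$name else ".",
                      if ("score" %in% names(gi)) gi$score else 0,
                      if ("strand" %in% names(gi)) gi$strand else ".")
  } else {
    out <- data.frame(gi$chrom, gi$start, gi$end)
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- gene models ------------------------------------------------------------

#' Construct a gene model table
#'
#' @param gene_id character ids.
#' @param chrom,start,end,strand gene body interval (0-based half-open);
#'   strand must be "+" or "-" for promoter logic to work downstream.
#' @param tss transcription start site (bp), must lie in `[start, end]`.
#' @param intron_length_bp total intron length (bp), >= 0.
#' @param biotype gene biotype, default "protein_coding".
#' @return data.frame of gene models.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand, tss,
                        intron_length_bp, biotype = "protein_coding") {
  gm <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), tss = as.integer(tss),
                   intron_length_bp = as.integer(intron_length_bp),
                   biotype = rep_len(biotype, length(gene_id)),
                   stringsAsFactors = FALSE)
  validate_intervals(gm)
  if (any(gm$tss < gm$start | gm$tss > gm$end))
    stop("tss must lie within the gene interval")
  if (any(gm$intron_length_bp < 0)) stop("intron_length_bp must be >= 0")
  gm
}

# ---- cell matrix ------------------------------------------------------------

#' Construct a cell-by-feature count matrix container
#'
#' @param counts sparse (or dense) non-negative integer matrix,
#'   cells x features.
#' @param modality one of "chic", "rna_spliced", "rna_unspliced".
#' @param mark for chic, optionally "H3K27me3" or "H3K4me1".
#' @param cell_meta data.frame, one row per cell; must contain `barcode`.
#' @param feature_meta data.frame, one row per feature; must contain
#'   `feature_id`.
#' @return object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, modality, mark = NULL,
                        cell_meta = NULL, feature_meta = NULL) {
  modality <- match.arg(modality, c("chic", "rna_spliced", "rna_unspliced"))
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  vals <- counts@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals))))
    stop("counts must be non-negative integers")
  if (is.null(cell_meta))
    cell_meta <- data.frame(barcode = paste0("cell", seq_len(nrow(counts))))
  if (is.null(feature_meta))
    feature_meta <- data.frame(feature_id = paste0("f", seq_len(ncol(counts))))
  if (nrow(cell_meta) != nrow(counts))
    stop("cell_meta rows must match matrix rows")
  if (nrow(feature_meta) != ncol(counts))
    stop("feature_meta rows must match matrix columns")
  rownames(counts) <- cell_meta$barcode
  colnames(counts) <- feature_meta$feature_id
  structure(list(counts = counts, modality = modality, mark = mark,
                 cell_meta = cell_meta, feature_meta = feature_meta),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d features [%s%s], %.2f%% nonzero\n",
              nrow(x$counts), ncol(x$counts), x$modality,
              if (!is.null(x$mark)) paste0("/", x$mark) else "",
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Subset a cell_matrix by cells and/or features
#' @param m cell_matrix.
#' @param cells,features logical/integer index vectors (NULL keeps all).
#' @return cell_matrix.
#' @export
subset_cells <- function(m, cells = NULL, features = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(m$counts))
  if (is.null(features)) features <- seq_len(ncol(m$counts))
  cell_matrix(m$counts[cells, features, drop = FALSE], m$modality, m$mark,
              m$cell_meta[cells, , drop = FALSE],
              m$feature_meta[features, , drop = FALSE])
}

#' Read a cell matrix from MatrixMarket + barcode/feature lists
#'
#' Expects the matrix stored cells x features (rows = barcodes). Dimensions
#' are validated against the barcode and feature files; `meta` (optional
#' TSV with a `barcode` column) is joined onto the cells.
#'
#' @param mtx_path .mtx file.
#' @param barcodes one-column (or headered TSV) barcode list.
#' @param features TSV of feature metadata; first column = feature id if no
#'   `feature_id` column present.
#' @param meta optional cell-metadata TSV with a `barcode` column.
#' @param modality,mark passed to [cell_matrix()].
#' @return `cell_matrix`.
#' @export
read_cell_matrix <- function(mtx_path, barcodes, features, meta = NULL,
                             modality = "chic", mark = NULL) {
  counts <- Matrix::readMM(mtx_path)
  bc <- data.table::fread(barcodes, header = FALSE, data.table = FALSE)
  if (identical(tolower(bc[1, 1]), "barcode")) bc <- bc[-1, , drop = FALSE]
  fx <- data.table::fread(features, header = TRUE, data.table = FALSE)
  if (!"feature_id" %in% names(fx)) names(fx)[1] <- "feature_id"
  if (nrow(counts) != nrow(bc))
    stop(sprintf("barcode file has %d rows but matrix has %d rows",
                 nrow(bc), nrow(counts)))
  if (ncol(counts) != nrow(fx))
    stop(sprintf("feature file has %d rows but matrix has %d columns",
                 nrow(fx), ncol(counts)))
  cm <- data.frame(barcode = as.character(bc[[1]]))
  if (!is.null(meta)) {
    md <- data.table::fread(meta, header = TRUE, data.table = FALSE)
    if (!"barcode" %in% names(md)) stop("cell metadata must have a 'barcode' column")
    cm <- merge(cm, md, by = "barcode", all.x = TRUE, sort = FALSE)
    cm <- cm[match(as.character(bc[[1]]), cm$barcode), , drop = FALSE]
    rownames(cm) <- NULL
  }
  cell_matrix(counts, modality, mark, cm, fx)
}

#' Write a cell matrix as MatrixMarket + barcode/feature TSVs
#'
#' @param m cell_matrix.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, named vector of written paths.
#' @export
write_cell_matrix <- function(m, dir, prefix) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mtx = file.path(dir, paste0(prefix, ".mtx")),
             barcodes = file.path(dir, paste0(prefix, ".barcodes.tsv")),
             features = file.path(dir, paste0(prefix, ".features.tsv")),
             meta = file.path(dir, paste0(prefix, ".cell_meta.tsv")))
  Matrix::writeMM(m$counts, paths["mtx"])
  data.table::fwrite(data.frame(m$cell_meta$barcode), paths["barcodes"],
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(m$feature_meta, paths["features"], sep = "\t")
  data.table::fwrite(m$cell_meta, paths["meta"], sep = "\t")
  invisible(paths)
}
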