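# Metacell aggregation: group transcriptionally similar cells into pooled
# pseudo-replicates. The grouping itself is seeded k-means on a
# caller-provided embedding with nearest-centroid assignment (the
# archetype-based aggregator used on the real data is interchangeable:
# `metacell_set()` accepts any externally computed assignment). The
# mark-balancing, annotation, and aggregation contracts downstream are what
# the analyses rely on.

#' Build a metacell set from an assignment vector
#'
#' @param assignment integer metacell id per cell, NA = unassigned.
#' @param n_metacells number of metacells (defaults to max id).
#' @return list of class `metacell_set`.
#' @export
metacell_set <- function(assignment, n_metacells = NULL) {
  if (is.null(n_metacells)) n_metacells <- max(assignment, na.rm = TRUE)
  structure(list(assignment = as.integer(assignment),
                 n_metacells = as.integer(n_metacells),
                 annotations = NULL, mark_counts = NULL),
            class = "metacell_set")
}

#' Assign cells to metacells by seeded k-means
#'
#' Runs k-means (`nc` centers) on the embedding, then re-assigns each cell
#' to its nearest centroid so groups are contiguous in embedding space.
#' Deterministic given `seed`.
#'
#' @param embedding cells x dims real matrix.
#' @param nc number of metacells, < number of cells.
#' @param seed integer RNG seed.
#' @param iter_max,nstart passed to [stats::kmeans()].
#' @return `metacell_set`.
#' @export
assign_metacells <- function(embedding, nc, seed = 1, iter_max = 100,
                             nstart = 5) {
  embedding <- as.matrix(embedding)
  if (nc >= nrow(embedding)) stop("nc must be < number of cells")
  force(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(embedding, centers = nc,
                                       iter.max = iter_max, nstart = nstart))
  # nearest-centroid reassignment (k-means is already consistent at
  # convergence; enforce the contract explicitly)
  d2 <- outer(rowSums(embedding^2), rep(1, nc)) -
    2 * embedding %*% t(km$centers) +
    outer(rep(1, nrow(embedding)), rowSums(km$centers^2))
  metacell_set(max.col(-d2, ties.method = "first"), nc)
}

#' Balance histone-mark membership within metacells
#'
#' Within each metacell, cells of the majority mark are randomly
#' downsampled (seeded) to the minority count; metacells whose smaller mark
#' count is below `min_cells` are dropped entirely. Dropped/downsampled
#' cells become unassigned (NA).
#'
#' @param ms `metacell_set`.
#' @param marks character vector per cell with exactly two levels.
#' @param min_cells minimum per-mark membership (default 20).
#' @param seed RNG seed for the downsampling.
#' @return `metacell_set` with balanced assignment and a `mark_counts`
#'   matrix (metacell x mark) of retained members.
#' @export
balance_marks <- function(ms, marks, min_cells = 20, seed = 1) {
  lev <- sort(unique(as.character(marks)))
  if (length(lev) != 2) {
    if (length(lev) < 2) {
      warning("only one mark present; all metacells dropped")
      ms$assignment <- rep(NA_integer_, length(ms$assignment))
      ms$mark_counts <- matrix(0L, ms$n_metacells, length(lev),
                               dimnames = list(NULL, lev))
      return(ms)
    }
    stop("marks must have exactly 2 levels")
  }
  force(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assign <- ms$assignment
  out <- rep(NA_integer_, length(assign))
  mark_counts <- matrix(0L, ms$n_metacells, 2, dimnames = list(NULL, lev))
  for (mc in seq_len(ms$n_metacells)) {
    i1 <- which(!is.na(assign) & assign == mc & marks == lev[1])
    i2 <- which(!is.na(assign) & assign == mc & marks == lev[2])
    nmin <- min(length(i1), length(i2))
    if (nmin < min_cells) next
    if (length(i1) > nmin) i1 <- sort(sample(i1, nmin))
    if (length(i2) > nmin) i2 <- sort(sample(i2, nmin))
    out[c(i1, i2)] <- mc
    mark_counts[mc, ] <- c(length(i1), length(i2))
  }
  ms$assignment <- out
  ms$mark_counts <- mark_counts
  ms
}

#' Annotate metacells with modal label and mean latent time
#'
#' The modal cell-type label wins by count; ties are broken
#' lexicographically and flagged. Latent time is the arithmetic mean over
#' assigned members.
#'
#' @param ms `metacell_set`.
#' @param labels per-cell label vector.
#' @param latent_time per-cell latent time.
#' @param timepoints optional per-cell timepoint; modal value recorded.
#' @return `metacell_set` with an `annotations` data.frame
#'   (metacell, label, label_tie, mean_latent_time, n_cells[, timepoint]).
#' @export
annotate_metacells <- function(ms, labels, latent_time, timepoints = NULL) {
  ann <- lapply(seq_len(ms$n_metacells), function(mc) {
    idx <- which(!is.na(ms$assignment) & ms$assignment == mc)
    if (!length(idx)) {
      return(data.frame(metacell = mc, label = NA_character_,
                        label_tie = FALSE, mean_latent_time = NA_real_,
                        n_cells = 0L))
    }
    tab <- sort(table(as.character(labels[idx])), decreasing = TRUE)
    winners <- names(tab)[tab == max(tab)]
    data.frame(metacell = mc, label = sort(winners)[1],
               label_tie = length(winners) > 1,
               mean_latent_time = mean(latent_time[idx]),
               n_cells = length(idx))
  })
  ann <- do.call(rbind, ann)
  if (!is.null(timepoints)) {
    ann$timepoint <- vapply(seq_len(ms$n_metacells), function(mc) {
      idx <- which(!is.na(ms$assignment) & ms$assignment == mc)
      if (!length(idx)) return(NA_character_)
      tab <- sort(table(as.character(timepoints[idx])), decreasing = TRUE)
      sort(names(tab)[tab == max(tab)])[1]
    }, character(1))
  }
  ms$annotations <- ann
  ms
}

#' Aggregate counts over metacells
#'
#' Column sums of member cells per metacell; unassigned cells are excluded,
#' so totals over metacells never exceed totals over cells.
#'
#' @param m `cell_matrix` (or sparse matrix, cells x features).
#' @param ms `metacell_set`; assignment indexed by `cells` if the matrix
#'   covers a subset of the assignment vector.
#' @param cells optional index mapping matrix rows into `ms$assignment`.
#' @return dense metacell x feature matrix of summed counts (all
#'   `ms$n_metacells` rows; empty metacells are all-zero).
#' @export
aggregate_counts <- function(m, ms, cells = NULL) {
  counts <- if (inherits(m, "cell_matrix")) m$counts else m
  assign <- ms$assignment
  if (!is.null(cells)) assign <- assign[cells]
  if (length(assign) != nrow(counts))
    stop("assignment does not cover the matrix cells")
  keep <- !is.na(assign)
  ind <- Matrix::sparseMatrix(i = assign[keep], j = which(keep), x = 1,
                              dims = c(ms$n_metacells, nrow(counts)))
  out <- as.matrix(ind %*% counts)
  colnames(out) <- colnames(counts)
  out
}

# save/restore global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
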