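#' Collapse a probe-level matrix to gene level by maximal IQR
#'
#' When several probes map to one gene symbol, the probe with the largest
#' interquartile range of expression across all samples (type-7
#' linear-interpolation quantiles) represents the gene; exact IQR ties are
#' broken toward the lexicographically smaller probe ID so the collapse is
#' reproducible. Probes absent from the map are dropped; mapped probes
#' absent from the matrix are ignored with a warning.
#'
#' @param matrix numeric probe x sample matrix with probe IDs as rownames.
#' @param map data frame (or named character vector) mapping `probe_id` to
#'   `gene_symbol`, many probes to one gene.
#' @return A gene x sample matrix with one row per gene symbol, rows
#'   ordered by gene symbol.
#' @export
collapse_probes <- function(matrix, map) {
  if (!is.matrix(matrix) || nrow(matrix) == 0L)
    stop("'matrix' must be a nonempty probe x sample matrix", call. = FALSE)
  if (is.data.frame(map)) {
    if (!all(c("probe_id", "gene_symbol") %in% names(map)))
      stop("'map' needs columns probe_id and gene_symbol", call. = FALSE)
    map <- setNames(as.character(map$gene_symbol), as.character(map$probe_id))
  }
  if (length(map) == 0L)
    stop("probe map is empty", call. = FALSE)
  missing <- setdiff(names(map), rownames(matrix))
  if (length(missing))
    warning(sprintf("%d mapped probe(s) not present in the matrix were ignored",
                    length(missing)))
  map <- map[names(map) %in% rownames(matrix)]
  if (length(map) == 0L)
    stop("no mapped probe is present in the matrix", call. = FALSE)

  iqr <- apply(matrix[names(map), , drop = FALSE], 1L,
               function(x) IQR(x, type = 7, na.rm = TRUE))
  # order: gene, then IQR descending, then probe ID ascending -> first per gene wins
  ord <- order(map, -iqr, names(map))
  keep <- !duplicated(map[ord])
  probes <- names(map)[ord][keep]
  out <- matrix[probes, , drop = FALSE]
  rownames(out) <- map[probes]
  out
}

#' Screen sample outliers on the first two principal components
#'
#' Projects samples onto the first two principal components of the
#' expression matrix and removes samples lying more than `z_cut`
#' robust-z units (median/MAD) from the center on either component. A
#' removal that would leave fewer than two samples in a group is vetoed:
#' the sample stays in the dataset and is reported as flagged.
#'
#' @param ds a [study_dataset()] with at least 4 samples.
#' @param z_cut positive robust-z threshold (default 5).
#' @return A list with `dataset` (screened [study_dataset()]), `removed`
#'   and `flagged` (character vectors of sample IDs).
#' @export
screen_outliers <- function(ds, z_cut = 5) {
  stopifnot(inherits(ds, "study_dataset"))
  if (!is.numeric(z_cut) || length(z_cut) != 1L || z_cut <= 0)
    stop("'z_cut' must be a positive number", call. = FALSE)
  if (ncol(ds$matrix) < 4L)
    stop("outlier screening needs at least 4 samples", call. = FALSE)

  pc <- prcomp(t(ds$matrix), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  out <- rep(FALSE, nrow(scores))
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    scale_j <- mad(s)
    if (scale_j == 0) next  # degenerate axis: all samples identical there
    out <- out | abs(s - median(s)) / scale_j > z_cut
  }
  samples <- colnames(ds$matrix)
  candidates <- samples[out]

  removed <- character(0); flagged <- character(0)
  groups <- setNames(ds$groups, samples)
  for (s in candidates) {
    g <- groups[[s]]
    n_left <- sum(groups[setdiff(samples, c(removed, s))] == g)
    if (n_left >= 2L) removed <- c(removed, s) else flagged <- c(flagged, s)
  }
  keep <- setdiff(samples, removed)
  screened <- study_dataset(ds$study_id,
                            ds$matrix[, keep, drop = FALSE],
                            groups[keep], ds$platform_tag)
  list(dataset = screened, removed = removed, flagged = flagged)
}

#' Cross-study common gene universe
#'
#' The intersection of the (post-collapse) gene sets of all studies; the
#' universe on which meta-analysis and network scoring operate.
#'
#' @param studies list of [study_dataset()] objects.
#' @return Sorted character vector of gene IDs present in every study.
#' @export
common_genes <- function(studies) {
  stopifnot(length(studies) >= 1L)
  sets <- lapply(studies, function(s) rownames(s$matrix))
  sort(Reduce(intersect, sets))
}
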