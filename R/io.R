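#' Read and write the pipeline's plain-text formats
#'
#' Expression matrices travel as TSV with gene IDs in the first column and
#' sample IDs as header; phenotypes as a two-column TSV (`sample_id`,
#' `group` in high/low); networks as a two-column gene-ID edge list (TSV)
#' or SIF; gene sets as GMT.
#'
#' @param path file path.
#' @param ds,matrix,groups,graph objects to write.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_study_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "study_dataset"))
  df <- data.frame(gene = rownames(ds$matrix), ds$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pheno <- data.frame(sample_id = colnames(ds$matrix), group = ds$groups,
                      stringsAsFactors = FALSE)
  write.table(pheno, pheno_path(path), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

pheno_path <- function(path) sub("(\\.[^.]+)?$", ".pheno.tsv",
                                 sub("\\.tsv$", "", path))

#' @rdname pipeline_io
#' @param study_id,platform_tag metadata for the rebuilt dataset.
#' @export
read_study_tsv <- function(path, study_id = basename(path),
                           platform_tag = "unknown") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  pheno <- read.delim(pheno_path(path), stringsAsFactors = FALSE)
  groups <- setNames(pheno$group, pheno$sample_id)[colnames(mat)]
  study_dataset(study_id, mat, unname(groups), platform_tag)
}

#' @rdname pipeline_io
#' @export
write_network_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.table(data.frame(from = el[, 1], to = el[, 2]), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_network <- function(path) {
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    rows <- strsplit(readLines(path), "[ \t]+")
    el <- do.call(rbind, lapply(rows[lengths(rows) >= 3L],
                                function(r) cbind(r[1], r[-(1:2)])))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  }
  igraph::simplify(g)
}

#' Read a GMT gene-set collection
#'
#' Each GMT line is `set_name <tab> description <tab> gene1 <tab> ...`.
#'
#' @param path GMT file path.
#' @return Named list of gene-ID character vectors.
#' @export
read_gmt <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  rows <- rows[lengths(rows) >= 3L]
  if (length(rows) == 0L) stop("no valid GMT records in file", call. = FALSE)
  setNames(lapply(rows, function(r) unique(r[-(1:2)])),
           vapply(rows, `[[`, character(1), 1L))
}

#' Write a module as GraphML plus a TSV of node attributes
#'
#' @param module a `network_module`.
#' @param path_graphml,path_tsv output paths (either may be `NULL`).
#' @export
write_module <- function(module, path_graphml = NULL, path_tsv = NULL) {
  stopifnot(inherits(module, "network_module"))
  if (!is.null(path_graphml)) {
    g <- igraph::graph_from_data_frame(
      module$edges, directed = FALSE,
      vertices = data.frame(name = module$nodes))
    igraph::V(g)$score <- unname(module$scores[igraph::V(g)$name])
    if (!is.null(module$node_freq))
      igraph::V(g)$frequency <- unname(module$node_freq[igraph::V(g)$name])
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  if (!is.null(path_tsv)) {
    df <- data.frame(gene = module$nodes,
                     score = unname(module$scores[module$nodes]),
                     stringsAsFactors = FALSE)
    if (!is.null(module$node_freq))
      df$frequency <- unname(module$node_freq[module$nodes])
    write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(module)
}

#' Reference summary tables for the six-study BMD meta-analysis
#'
#' Published reference values bundled as plain-text data: `bmd_studies()`
#' returns the per-study design of a six-study two-group (high vs low
#' bone mineral density) microarray meta-analysis (sample sizes, removed
#' outliers, platform, tissue); `bmd_candidates()` returns the meta-analysis
#' summary statistics (pooled SMD, z, Fisher statistic and p-values, and
#' gene-level GWAS replication p-values) for its five candidate genes.
#' They serve as fixed inputs for consistency checks of the analytic
#' machinery (chi-squared tail reproduction, z = SMD/SE coherence,
#' sample-size bookkeeping).
#'
#' @return A data frame.
#' @export
bmd_studies <- function() {
  read.delim(system.file("extdata", "bmd_studies.tsv",
                         package = "metamodule"),
             stringsAsFactors = FALSE)
}

#' @rdname bmd_studies
#' @export
bmd_candidates <- function() {
  read.delim(system.file("extdata", "bmd_candidates.tsv",
                         package = "metamodule"),
             stringsAsFactors = FALSE)
}
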