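#' Pipeline configuration
#'
#' Collects file paths and parameters for [run_pipeline()]. Can be built
#' directly or loaded from a YAML file with the same field names.
#'
#' @param expression character vector of per-study expression TSV paths
#'   (each with a sibling `.pheno.tsv`, see [write_study_tsv()]).
#' @param network path to the edge-list TSV or SIF network.
#' @param out_dir output directory (created if missing).
#' @param gene_sets optional GMT path for enrichment.
#' @param probe_map optional probe-map TSV (`probe_id`, `gene_symbol`);
#'   when given, matrices are collapsed to gene level first.
#' @param snp_assoc optional SNP association TSV (`snp_id`, `gene`,
#'   `trait`, `p`) for gene-level GWAS lookup of the candidates.
#' @param s0,n_perm,fdr_bum,n_iter,phi,resample,z_cut,alpha analysis
#'   parameters, passed through to the corresponding stages.
#' @param screen run the PCA outlier screen (default `TRUE`).
#' @param seed integer master seed; each random stage draws from a stream
#'   derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, network, out_dir,
                            gene_sets = NULL, probe_map = NULL,
                            snp_assoc = NULL, s0 = "auto", n_perm = 1000L,
                            fdr_bum = 0.001, n_iter = 100L, phi = 0.5,
                            resample = "bootstrap", z_cut = 5,
                            alpha = 0.05, screen = TRUE, seed = 1L) {
  cfg <- list(expression = expression, network = network, out_dir = out_dir,
              gene_sets = gene_sets, probe_map = probe_map,
              snp_assoc = snp_assoc, s0 = s0, n_perm = as.integer(n_perm),
              fdr_bum = fdr_bum, n_iter = as.integer(n_iter), phi = phi,
              resample = resample, z_cut = z_cut, alpha = alpha,
              screen = isTRUE(screen), seed = as.integer(seed))
  for (f in c(cfg$expression, cfg$network, cfg$gene_sets, cfg$probe_map,
              cfg$snp_assoc)) {
    if (!file.exists(f))
      stop(sprintf("input file not found: %s", f), call. = FALSE)
  }
  if (cfg$n_perm < 1L || cfg$n_iter < 1L || cfg$fdr_bum <= 0 ||
      cfg$fdr_bum >= 1 || cfg$phi <= 0 || cfg$phi >= 1 || cfg$z_cut <= 0)
    stop("pipeline parameter out of range", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields above.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full network-based meta-analysis pipeline
#'
#' Executes preprocess (optional probe collapse and outlier screen),
#' per-study SAM with permutation p-values, gene-level meta-analysis
#' ([meta_deg()]), consensus module detection ([consensus_module()]),
#' candidate selection and (optionally) enrichment and GWAS lookup,
#' writing every stage's table plus a JSON run manifest to `out_dir`.
#' Outputs are a pure function of the config (including its seed).
#'
#' @param config a [pipeline_config()] or a YAML path.
#' @return Invisibly, a list with the fitted objects (`studies`, `meta`,
#'   `module`, `candidates`, `enrichment`, `gwas`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  stage_log("preprocess", "reading %d studies", length(config$expression))
  studies <- lapply(seq_along(config$expression), function(i) {
    read_study_tsv(config$expression[i], study_id = sprintf("study%d", i))
  })
  removed <- list()
  if (!is.null(config$probe_map)) {
    pm <- read.delim(config$probe_map, stringsAsFactors = FALSE)
    studies <- lapply(studies, function(ds) {
      study_dataset(ds$study_id, collapse_probes(ds$matrix, pm),
                    ds$groups, ds$platform_tag)
    })
  }
  if (config$screen) {
    studies <- lapply(studies, function(ds) {
      scr <- screen_outliers(ds, z_cut = config$z_cut)
      removed[[ds$study_id]] <<- scr$removed
      scr$dataset
    })
  }
  universe <- common_genes(studies)
  stage_log("preprocess", "common gene universe: %d genes", length(universe))

  stage_log("meta", "SAM + meta-analysis (n_perm = %d)", config$n_perm)
  meta <- meta_deg(studies, n_perm = config$n_perm, s0 = config$s0,
                   seed = config$seed + 100L)
  write.table(meta$table, file.path(config$out_dir, "meta_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(meta$per_study)) {
    write.table(meta$per_study[[i]],
                file.path(config$out_dir,
                          sprintf("sam_%s.tsv", names(meta$per_study)[i])),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  stage_log("module", "consensus module (n_iter = %d, fdr = %g)",
            config$n_iter, config$fdr_bum)
  network <- read_network(config$network)
  module <- consensus_module(studies, network, n_iter = config$n_iter,
                             fdr = config$fdr_bum, resample = config$resample,
                             phi = config$phi, n_perm = config$n_perm,
                             s0 = config$s0, seed = config$seed + 200L)
  write_module(module,
               path_graphml = file.path(config$out_dir, "module.graphml"),
               path_tsv = file.path(config$out_dir, "module.tsv"))

  stage_log("select", "candidate gene selection (alpha = %g)", config$alpha)
  candidates <- select_candidates(meta, module, alpha = config$alpha)
  write.table(candidates, file.path(config$out_dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  enrichment <- NULL
  if (!is.null(config$gene_sets) && length(module$nodes)) {
    stage_log("enrich", "hypergeometric enrichment")
    enrichment <- hypergeom_enrich(module$nodes, read_gmt(config$gene_sets),
                                   background = universe)
    write.table(enrichment, file.path(config$out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gwas <- NULL
  if (!is.null(config$snp_assoc) && nrow(candidates)) {
    stage_log("gwas", "gene-level GWAS lookup")
    gwas <- gene_level_gwas_p(read.delim(config$snp_assoc,
                                         stringsAsFactors = FALSE),
                              candidates$gene, alpha = config$alpha)
    write.table(gwas, file.path(config$out_dir, "gwas_gene_level.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(packageVersion("metamodule")),
    seed = config$seed,
    parameters = config[c("s0", "n_perm", "fdr_bum", "n_iter", "phi",
                          "resample", "z_cut", "alpha", "screen")],
    inputs = config[c("expression", "network", "gene_sets", "probe_map",
                      "snp_assoc")],
    removed_outliers = removed,
    n_common_genes = length(universe),
    n_meta_genes = nrow(meta$table),
    module_nodes = length(module$nodes),
    module_edges = nrow(module$edges),
    n_candidates = nrow(candidates))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("done", "outputs in %s (%.1f s)", config$out_dir,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(studies = studies, meta = meta, module = module,
                 candidates = candidates, enrichment = enrichment,
                 gwas = gwas, manifest = manifest))
}
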