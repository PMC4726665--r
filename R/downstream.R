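#' Hypergeometric over-representation test of a gene set collection
#'
#' For each set, tests whether the query genes overlap it more than
#' expected under sampling without replacement from the background:
#' `p = P(X >= k)` for X hypergeometric(N background, m set genes,
#' n query genes). Adjustment is Bonferroni over the number of sets
#' tested. Query genes outside the background are dropped with a warning;
#' sets are restricted to the background.
#'
#' @param query character vector of query gene IDs (e.g. module nodes).
#' @param sets named list of gene-ID vectors (e.g. from [read_gmt()]).
#' @param background character vector, the gene universe (defaults should
#'   be the cross-study common universe, not the whole genome).
#' @return Data frame sorted by p: `set_name`, `k_overlap`, `m_set`,
#'   `n_query`, `N_background`, `p`, `p_adj`, `overlap_genes`.
#' @export
hypergeom_enrich <- function(query, sets, background) {
  if (length(query) == 0L) stop("empty query gene set", call. = FALSE)
  if (length(sets) == 0L || is.null(names(sets)))
    stop("'sets' must be a nonempty named list", call. = FALSE)
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside))
    warning(sprintf("%d query gene(s) outside the background were dropped",
                    length(outside)))
  query <- intersect(unique(query), background)
  if (length(query) == 0L)
    stop("no query gene lies in the background", call. = FALSE)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), background)
    m <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    # upper tail P(X >= k); k = 0 gives 1 by convention
    p <- if (k == 0L) 1 else phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    data.frame(set_name = nm, k_overlap = k, m_set = m, n_query = n,
               N_background = N, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * length(sets))
  out <- out[order(out$p, out$set_name),
             c("set_name", "k_overlap", "m_set", "n_query", "N_background",
               "p", "p_adj", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Select candidate genes from meta-analysis and module membership
#'
#' Applies the three-way gate: effect-size meta-analysis p < 0.05, AND
#' Fisher combined p < 0.05, AND membership in the module. Output is
#' sorted by Fisher p and invariant to the row order of the input table.
#'
#' @param meta a [meta_deg()] fit or its `table` data frame (columns
#'   `gene`, `es_p`, `fisher_p`).
#' @param module a `network_module` / `consensus_module`, or a character
#'   vector of module genes.
#' @param alpha significance level for both p-value criteria.
#' @return Data frame of selected genes (subset of the meta table rows).
#' @export
select_candidates <- function(meta, module, alpha = 0.05) {
  tab <- if (inherits(meta, "metadeg")) meta$table else meta
  stopifnot(all(c("gene", "es_p", "fisher_p") %in% names(tab)))
  nodes <- if (inherits(module, "network_module")) module$nodes
           else as.character(module)
  sel <- tab$es_p < alpha & tab$fisher_p < alpha & tab$gene %in% nodes
  out <- tab[sel, , drop = FALSE]
  out <- out[order(out$fisher_p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-level GWAS p-values from SNP associations
#'
#' Collapses SNP-level association p-values to the gene level by taking,
#' per gene and trait, the most significant (minimum) SNP p-value. A gene
#' is flagged associated when its minimum p is at or below `alpha` for at
#' least one trait. Genes with no SNP get `NA`, not 1.
#'
#' @param assocs data frame with columns `snp_id`, `gene`, `trait`, `p`.
#' @param genes character vector of genes to report.
#' @param alpha association threshold (default 0.05, nominal).
#' @return Data frame: `gene`, one `p_<trait>` column per trait, and
#'   `associated` (logical).
#' @export
gene_level_gwas_p <- function(assocs, genes, alpha = 0.05) {
  stopifnot(is.data.frame(assocs),
            all(c("snp_id", "gene", "trait", "p") %in% names(assocs)))
  if (nrow(assocs) == 0L) stop("empty SNP association table", call. = FALSE)
  if (anyNA(assocs$p) || any(assocs$p <= 0) || any(assocs$p > 1))
    stop("all SNP p-values must lie in (0, 1]", call. = FALSE)
  traits <- sort(unique(as.character(assocs$trait)))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (tr in traits) {
    sub <- assocs[assocs$trait == tr, ]
    mins <- tapply(sub$p, sub$gene, min)
    out[[paste0("p_", tr)]] <- as.numeric(mins[genes])
  }
  pcols <- as.matrix(out[, paste0("p_", traits), drop = FALSE])
  out$associated <- apply(pcols, 1L,
                          function(x) any(!is.na(x) & x <= alpha))
  out
}
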