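#' SAM relative-difference scores
#'
#' Computes, per gene, the SAM score `d = (mean_high - mean_low) / (s + s0)`
#' where `s` is the pooled standard error of the mean difference (the
#' equal-variance two-sample t denominator) and `s0` is the exchangeability
#' ("fudge") constant that damps scores of low-variance genes. With
#' `s0 = 0`, `d` is exactly the equal-variance two-sample t statistic.
#'
#' @param ds a [study_dataset()] with at least 2 samples per group.
#' @param s0 non-negative number, or `"auto"` (default) for the 5th
#'   percentile of the gene-wise standard errors.
#' @return A data frame with one row per gene: `gene`, `d`, `mean_high`,
#'   `mean_low`, `se`, plus the `s0` used as an attribute.
#' @export
sam_scores <- function(ds, s0 = "auto") {
  stopifnot(inherits(ds, "study_dataset"))
  st <- group_stats(ds$matrix, ds$groups)
  if (identical(s0, "auto")) {
    s0 <- unname(quantile(st$se, 0.05, type = 7))
  } else if (!is.numeric(s0) || length(s0) != 1L || s0 < 0) {
    stop("'s0' must be \"auto\" or a single non-negative number", call. = FALSE)
  }
  d <- (st$mean_high - st$mean_low) / (st$se + s0)
  res <- data.frame(gene = rownames(ds$matrix), d = unname(d),
                    mean_high = unname(st$mean_high),
                    mean_low = unname(st$mean_low),
                    se = unname(st$se), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "s0") <- s0
  res
}

# d-scores for all genes for an arbitrary label assignment, vectorized.
# hi is a logical vector over samples; s0 is fixed (not re-tuned per perm).
sam_d_for_labels <- function(mat, hi, s0) {
  n1 <- sum(hi); n2 <- sum(!hi)
  m1 <- rowMeans(mat[, hi, drop = FALSE])
  m2 <- rowMeans(mat[, !hi, drop = FALSE])
  v1 <- (rowSums(mat[, hi, drop = FALSE]^2) - n1 * m1^2) / (n1 - 1L)
  v2 <- (rowSums(mat[, !hi, drop = FALSE]^2) - n2 * m2^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  se <- sqrt(pmax(sp2, 0) * (1 / n1 + 1 / n2))
  (m1 - m2) / (se + s0)
}

#' SAM permutation p-values with a pooled null
#'
#' Permutes the group labels `n_perm` times, recomputes the SAM score for
#' every gene under each permutation, and pools all `n_perm * n_genes`
#' null scores into one empirical null. The two-sided p-value for gene g
#' is `(1 + #\{|d*| >= |d_g|\}) / (1 + n_perm * n_genes)`; the plus-one
#' smoothing keeps p strictly positive so downstream log-combination is
#' well defined. Pooling across genes is what lets a modest number of
#' permutations resolve p-values far below `1 / n_perm`.
#'
#' @inheritParams sam_scores
#' @param n_perm number of label permutations (the reference analysis
#'   design uses 1000).
#' @param seed integer seed; results are a pure function of it.
#' @return A data frame as in [sam_scores()] with an additional `p`
#'   column.
#' @export
sam_permutation_p <- function(ds, n_perm = 1000L, s0 = "auto", seed = 1L) {
  stopifnot_scalar_count(n_perm, "n_perm")
  obs <- sam_scores(ds, s0)
  s0_used <- attr(obs, "s0")
  n <- ncol(ds$matrix)
  hi_obs <- ds$groups == "high"
  n1 <- sum(hi_obs)
  null_abs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      hi <- logical(n)
      hi[sample.int(n, n1)] <- TRUE
      abs(sam_d_for_labels(ds$matrix, hi, s0_used))
    }, numeric(nrow(ds$matrix)))
  })
  null_sorted <- sort(as.numeric(null_abs))
  n_null <- length(null_sorted)
  # count of null |d*| >= |d_g| via binary search on the sorted pooled null
  n_ge <- n_null - findInterval(abs(obs$d), null_sorted, left.open = TRUE)
  obs$p <- (1 + n_ge) / (1 + n_null)
  attr(obs, "s0") <- s0_used
  attr(obs, "n_perm") <- as.integer(n_perm)
  obs
}
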