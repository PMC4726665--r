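#' Fisher's method for combining independent p-values
#'
#' Combines k independent p-values into the statistic `-2 * sum(log(p))`,
#' which follows a chi-squared distribution with `2k` degrees of freedom
#' under the joint null of uniform p-values.
#'
#' @param p_list numeric vector of p-values, each in (0, 1]. A zero is an
#'   error: upstream p-values must be smoothed away from 0 (see
#'   [sam_permutation_p()]).
#' @return A list with `statistic` and `p` (upper chi-squared tail).
#' @export
fisher_combine <- function(p_list) {
  if (length(p_list) == 0L)
    stop("empty p-value list", call. = FALSE)
  if (anyNA(p_list) || any(p_list <= 0) || any(p_list > 1))
    stop("all p-values must lie in (0, 1]; smooth zero p-values upstream",
         call. = FALSE)
  stat <- -2 * sum(log(p_list))
  list(statistic = stat,
       p = pchisq(stat, df = 2 * length(p_list), lower.tail = FALSE))
}

#' Standardized mean difference (Hedges' g) from group summaries
#'
#' Cohen's d `(mean_high - mean_low) / pooled SD` with Hedges'
#' small-sample correction `J = 1 - 3 / (4*(n1+n2-2) - 1)`, and its
#' sampling variance `J^2 * ((n1+n2)/(n1*n2) + d^2 / (2*(n1+n2-2)))`.
#' The correction matters at the group sizes (9--45) typical of the
#' two-group expression studies this package targets; set
#' `hedges = FALSE` for plain Cohen's d.
#'
#' @param n_high,n_low group sizes (each >= 2).
#' @param mean_high,mean_low group means (vectors allowed, per gene).
#' @param pooled_sd pooled standard deviation (> 0).
#' @param hedges apply the small-sample correction (default `TRUE`).
#' @return A list with `g` (effect) and `var` (its variance).
#' @export
smd_per_study <- function(n_high, n_low, mean_high, mean_low, pooled_sd,
                          hedges = TRUE) {
  if (n_high < 2L || n_low < 2L)
    stop("group sizes must be >= 2", call. = FALSE)
  if (any(pooled_sd <= 0))
    stop("pooled SD must be positive; flag constant genes upstream",
         call. = FALSE)
  m <- n_high + n_low - 2L
  d <- (mean_high - mean_low) / pooled_sd
  J <- if (hedges) 1 - 3 / (4 * m - 1) else 1
  list(g = J * d,
       var = J^2 * ((n_high + n_low) / (n_high * n_low) + d^2 / (2 * m)))
}

#' Cochran's Q and I-squared between-study heterogeneity
#'
#' `Q = sum(w_i * (g_i - g_bar)^2)` with inverse-variance weights and the
#' fixed-effect weighted mean `g_bar`; `I2 = max(0, (Q - (k-1)) / Q) * 100`
#' (defined as 0 when Q = 0).
#'
#' @param smds per-study effect sizes (k >= 2).
#' @param vars per-study effect variances (> 0).
#' @return A list with `Q` and `I2` (percent).
#' @export
heterogeneity <- function(smds, vars) {
  if (length(smds) < 2L || length(smds) != length(vars))
    stop("need k >= 2 matching effect sizes and variances", call. = FALSE)
  if (any(vars <= 0)) stop("variances must be positive", call. = FALSE)
  w <- 1 / vars
  gbar <- sum(w * smds) / sum(w)
  Q <- sum(w * (smds - gbar)^2)
  I2 <- if (Q > 0) max(0, (Q - (length(smds) - 1)) / Q) * 100 else 0
  list(Q = Q, I2 = I2)
}

#' Pool per-study effect sizes with heterogeneity-gated model choice
#'
#' The random-effects model is used when Cochran's Q is significant at
#' 0.05 (chi-squared with k-1 df) or I2 exceeds 50%; otherwise the
#' fixed-effects model. Fixed: inverse-variance weights. Random:
#' DerSimonian-Laird `tau2 = max(0, (Q - (k-1)) / (sum(w) -
#' sum(w^2)/sum(w)))`, weights `1 / (var + tau2)`. The z statistic is the
#' pooled effect over its standard error; `es_p` is the two-sided normal
#' tail.
#'
#' @inheritParams heterogeneity
#' @return A list with `model` ("fixed"/"random"), `pooled_smd`,
#'   `pooled_se`, `tau2`, `z`, `es_p`, `Q`, `I2`, `Q_p`.
#' @export
pool_effect <- function(smds, vars) {
  het <- heterogeneity(smds, vars)
  k <- length(smds)
  Q_p <- pchisq(het$Q, df = k - 1, lower.tail = FALSE)
  w <- 1 / vars
  tau2 <- 0
  model <- "fixed"
  if (Q_p < 0.05 || het$I2 > 50) {
    model <- "random"
    denom <- sum(w) - sum(w^2) / sum(w)
    tau2 <- if (denom > 0) max(0, (het$Q - (k - 1)) / denom) else 0
  }
  ws <- 1 / (vars + tau2)
  pooled <- sum(ws * smds) / sum(ws)
  se <- sqrt(1 / sum(ws))
  z <- pooled / se
  list(model = model, pooled_smd = pooled, pooled_se = se, tau2 = tau2,
       z = z, es_p = 2 * pnorm(-abs(z)), Q = het$Q, I2 = het$I2, Q_p = Q_p)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up adjustment (`stats::p.adjust`, method "BH"),
#' order-preserving on the original index.
#'
#' @param p_values p-values in (0, 1].
#' @return q-values in (0, 1].
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector", call. = FALSE)
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1))
    stop("all p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Gene-level meta-analysis across two-group expression studies
#'
#' The central fit of the package. For every gene in the cross-study
#' common universe it runs, per study, the SAM score with pooled-null
#' permutation p-values ([sam_permutation_p()]) and the standardized mean
#' difference ([smd_per_study()]); combines per-study p-values by
#' Fisher's method; pools effect sizes under the Q / I2 heterogeneity
#' gate ([pool_effect()]); and adjusts both combined p-values by
#' Benjamini-Hochberg.
#'
#' @param studies list of [study_dataset()] objects (k >= 2).
#' @param n_perm permutations per study for the SAM null.
#' @param s0 SAM fudge constant, `"auto"` or a number (see
#'   [sam_scores()]).
#' @param hedges apply Hedges' small-sample correction to the SMD.
#' @param es_p_method `"normal"` for the asymptotic two-sided normal
#'   p-value on z (default), or `"permutation"` for a pooled permutation
#'   null of z across genes (label permutations rerun through the full
#'   SMD pooling).
#' @param seed integer seed for all permutation draws.
#' @return An object of class `metadeg`: a list with `table` (one row per
#'   gene: per-gene Fisher and effect-size results), `per_study` (list of
#'   per-study SAM/SMD data frames), `k`, `genes`, `settings`, `call`.
#'   Genes with zero pooled SD in any study are dropped with a warning
#'   and listed in `dropped`.
#' @seealso [summary.metadeg()], [forest_data()], [select_candidates()]
#' @export
meta_deg <- function(studies, n_perm = 1000L, s0 = "auto", hedges = TRUE,
                     es_p_method = c("normal", "permutation"), seed = 1L) {
  es_p_method <- match.arg(es_p_method)
  if (length(studies) < 2L)
    stop("meta-analysis needs at least 2 studies", call. = FALSE)
  if (!all(vapply(studies, inherits, logical(1), "study_dataset")))
    stop("'studies' must be a list of study_dataset objects", call. = FALSE)
  genes <- common_genes(studies)
  if (length(genes) == 0L)
    stop("the cross-study common gene universe is empty", call. = FALSE)
  k <- length(studies)

  per_study <- vector("list", k)
  P <- G <- V <- matrix(NA_real_, length(genes), k,
                        dimnames = list(genes, NULL))
  bad <- rep(FALSE, length(genes))
  for (i in seq_len(k)) {
    ds <- studies[[i]]
    sub <- study_dataset(ds$study_id, ds$matrix[genes, , drop = FALSE],
                         ds$groups, ds$platform_tag)
    sam <- sam_permutation_p(sub, n_perm = n_perm, s0 = s0,
                             seed = seed + i)
    st <- group_stats(sub$matrix, sub$groups)
    zero_sd <- st$pooled_sd <= 0
    bad <- bad | zero_sd
    sd_safe <- ifelse(zero_sd, NA_real_, st$pooled_sd)
    smd <- smd_per_study(st$n_high, st$n_low, st$mean_high, st$mean_low,
                         ifelse(is.na(sd_safe), 1, sd_safe), hedges = hedges)
    sam$smd <- ifelse(zero_sd, NA_real_, smd$g)
    sam$smd_var <- ifelse(zero_sd, NA_real_, smd$var)
    per_study[[i]] <- sam
    P[, i] <- sam$p
    G[, i] <- sam$smd
    V[, i] <- sam$smd_var
    names(per_study)[i] <- ds$study_id
  }
  if (any(bad))
    warning(sprintf("%d gene(s) with zero pooled SD in some study were dropped",
                    sum(bad)))
  keep <- !bad
  genes_kept <- genes[keep]
  P <- P[keep, , drop = FALSE]
  G <- G[keep, , drop = FALSE]
  V <- V[keep, , drop = FALSE]

  fisher_stat <- -2 * rowSums(log(P))
  fisher_p <- pchisq(fisher_stat, df = 2 * k, lower.tail = FALSE)

  pool <- lapply(seq_along(genes_kept),
                 function(j) pool_effect(G[j, ], V[j, ]))
  tab <- data.frame(
    gene = genes_kept,
    fisher_stat = fisher_stat,
    fisher_p = fisher_p,
    fisher_q = bh_fdr(fisher_p),
    Q = vapply(pool, `[[`, numeric(1), "Q"),
    Q_p = vapply(pool, `[[`, numeric(1), "Q_p"),
    I2 = vapply(pool, `[[`, numeric(1), "I2"),
    model = vapply(pool, `[[`, character(1), "model"),
    tau2 = vapply(pool, `[[`, numeric(1), "tau2"),
    pooled_smd = vapply(pool, `[[`, numeric(1), "pooled_smd"),
    pooled_se = vapply(pool, `[[`, numeric(1), "pooled_se"),
    z = vapply(pool, `[[`, numeric(1), "z"),
    es_p = vapply(pool, `[[`, numeric(1), "es_p"),
    row.names = NULL, stringsAsFactors = FALSE)

  if (es_p_method == "permutation") {
    tab$es_p <- es_permutation_p(studies, genes_kept, tab$z,
                                 hedges = hedges, seed = seed + 1000L)
  }
  tab$es_q <- bh_fdr(tab$es_p)

  structure(list(table = tab, per_study = per_study, k = k,
                 genes = genes_kept, dropped = genes[bad],
                 settings = list(n_perm = as.integer(n_perm), s0 = s0,
                                 hedges = hedges, es_p_method = es_p_method,
                                 seed = as.integer(seed)),
                 call = match.call()),
            class = "metadeg")
}

# Pooled permutation null for the effect-size z statistic: permute labels
# within each study, recompute per-study SMDs and the pooled z for every
# gene, and pool the null z's across genes and permutations.
es_permutation_p <- function(studies, genes, z_obs, hedges, seed,
                             n_perm = 200L) {
  k <- length(studies)
  null_abs <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(b) {
      G <- V <- matrix(NA_real_, length(genes), k)
      for (i in seq_len(k)) {
        ds <- studies[[i]]
        mat <- ds$matrix[genes, , drop = FALSE]
        hi <- logical(ncol(mat))
        hi[sample.int(ncol(mat), sum(ds$groups == "high"))] <- TRUE
        gr <- ifelse(hi, "high", "low")
        st <- group_stats(mat, gr)
        sd_safe <- pmax(st$pooled_sd, 1e-12)
        smd <- smd_per_study(st$n_high, st$n_low, st$mean_high,
                             st$mean_low, sd_safe, hedges = hedges)
        G[, i] <- smd$g
        V[, i] <- smd$var
      }
      vapply(seq_along(genes),
             function(j) abs(pool_effect(G[j, ], V[j, ])$z), numeric(1))
    }))
  })
  null_sorted <- sort(null_abs)
  n_null <- length(null_sorted)
  n_ge <- n_null - findInterval(abs(z_obs), null_sorted, left.open = TRUE)
  (1 + n_ge) / (1 + n_null)
}

#' @export
print.metadeg <- function(x, ...) {
  cat(sprintf("Gene-level meta-analysis over %d studies, %d genes\n",
              x$k, nrow(x$table)))
  cat(sprintf("  model gate: %d fixed, %d random (Q p < 0.05 or I2 > 50%%)\n",
              sum(x$table$model == "fixed"), sum(x$table$model == "random")))
  cat(sprintf("  Fisher q < 0.05: %d genes; effect-size q < 0.05: %d genes\n",
              sum(x$table$fisher_q < 0.05), sum(x$table$es_q < 0.05)))
  invisible(x)
}

#' Summarize a gene-level meta-analysis fit
#'
#' @param object a [meta_deg()] fit.
#' @param alpha significance level for the reported counts.
#' @param ... unused.
#' @return An object of class `summary.metadeg`.
#' @export
summary.metadeg <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  top <- tab[order(tab$fisher_p), ]
  structure(list(k = object$k, n_genes = nrow(tab), alpha = alpha,
                 n_fisher_sig = sum(tab$fisher_q < alpha),
                 n_es_sig = sum(tab$es_q < alpha),
                 n_random = sum(tab$model == "random"),
                 top = head(top, 10L), settings = object$settings),
            class = "summary.metadeg")
}

#' @export
print.summary.metadeg <- function(x, ...) {
  cat(sprintf("Gene-level meta-analysis: %d genes, %d studies\n",
              x$n_genes, x$k))
  cat(sprintf("  q < %.3g: %d (Fisher), %d (effect size); random-effects genes: %d\n",
              x$alpha, x$n_fisher_sig, x$n_es_sig, x$n_random))
  cat("Top genes by Fisher p:\n")
  print(x$top[, c("gene", "fisher_stat", "fisher_p", "fisher_q",
                  "pooled_smd", "pooled_se", "z", "es_p", "model")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
#' @describeIn meta_deg pooled SMDs as a named vector.
#' @param object,... method arguments.
coef.metadeg <- function(object, ...) {
  setNames(object$table$pooled_smd, object$table$gene)
}

#' @export
as.data.frame.metadeg <- function(x, ...) x$table

#' Forest-plot data for one gene
#'
#' Per-study Hedges' g with 95% confidence bounds plus the pooled row, the
#' numbers a forest plot displays.
#'
#' @param fit a [meta_deg()] fit.
#' @param gene gene ID present in the fit.
#' @return Data frame with columns `study`, `g`, `ci_lo`, `ci_hi`,
#'   `weight_pct`; the last row is the pooled estimate.
#' @export
forest_data <- function(fit, gene) {
  stopifnot(inherits(fit, "metadeg"))
  row <- fit$table[fit$table$gene == gene, ]
  if (nrow(row) != 1L) stop(sprintf("gene '%s' not in fit", gene), call. = FALSE)
  g <- vapply(fit$per_study, function(s) s$smd[s$gene == gene], numeric(1))
  v <- vapply(fit$per_study, function(s) s$smd_var[s$gene == gene], numeric(1))
  w <- 1 / (v + row$tau2)
  zq <- qnorm(0.975)
  out <- data.frame(
    study = c(names(fit$per_study), "pooled"),
    g = c(g, row$pooled_smd),
    ci_lo = c(g - zq * sqrt(v), row$pooled_smd - zq * row$pooled_se),
    ci_hi = c(g + zq * sqrt(v), row$pooled_smd + zq * row$pooled_se),
    weight_pct = c(100 * w / sum(w), 100),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Forest plot for one gene of a meta-analysis fit
#'
#' @param x a [meta_deg()] fit.
#' @param gene gene ID to plot.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the [forest_data()] frame plotted.
#' @export
plot.metadeg <- function(x, gene, ...) {
  fd <- forest_data(x, gene)
  n <- nrow(fd)
  ys <- rev(seq_len(n))
  graphics::plot(fd$g, ys, xlim = range(fd$ci_lo, fd$ci_hi, 0),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "Standardized mean difference (95% CI)", ylab = "",
                 pch = c(rep(15, n - 1), 18),
                 main = sprintf("Forest plot: %s", gene), ...)
  graphics::segments(fd$ci_lo, ys, fd$ci_hi, ys)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = ys, labels = fd$study, las = 1, cex.axis = 0.8)
  invisible(fd)
}
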