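#' @keywords internal
"_PACKAGE"

#' @importFrom stats IQR coef density dhyper ks.test mad median na.omit optim
#'   p.adjust pchisq phyper pnorm prcomp qnorm quantile rbeta rnorm runif sd
#'   setNames var
#' @importFrom utils head read.delim write.table packageVersion
NULL

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Two-group summary statistics used by both SAM and SMD computations.
# Returns per-gene means, pooled SD and the pooled SE of the mean difference.
group_stats <- function(mat, groups) {
  hi <- groups == "high"
  lo <- groups == "low"
  n1 <- sum(hi); n2 <- sum(lo)
  if (n1 < 2L || n2 < 2L)
    stop("each group must contain at least 2 samples", call. = FALSE)
  m1 <- rowMeans(mat[, hi, drop = FALSE])
  m2 <- rowMeans(mat[, lo, drop = FALSE])
  v1 <- rowSums((mat[, hi, drop = FALSE] - m1)^2) / (n1 - 1L)
  v2 <- rowSums((mat[, lo, drop = FALSE] - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  list(n_high = n1, n_low = n2, mean_high = m1, mean_low = m2,
       pooled_sd = sqrt(sp2),
       se = sqrt(sp2 * (1 / n1 + 1 / n2)))
}

check_groups <- function(groups) {
  if (is.null(names(groups)) && !is.factor(groups) && !is.character(groups))
    stop("'groups' must be a character vector of 'high'/'low' labels",
         call. = FALSE)
  g <- as.character(groups)
  if (anyNA(g) || !all(g %in% c("high", "low")))
    stop("group labels must be 'high' or 'low' with no missing values",
         call. = FALSE)
  g
}
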