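#' Fit a beta-uniform mixture to a p-value distribution
#'
#' Models p-values as a mixture of uniform noise and a decreasing beta
#' signal component, with density `f(p) = lambda + (1 - lambda) * a *
#' p^(a - 1)` on (0, 1]. Parameters are estimated by maximum likelihood
#' with bounded L-BFGS-B from a 4 x 4 multi-start grid
#' (lambda0 in \{0.3, 0.5, 0.7, 0.9\}, a0 in \{0.1, 0.3, 0.5, 0.7\});
#' the best log-likelihood wins. Both parameters are constrained to
#' (1e-5, 1 - 1e-5).
#'
#' @param p_values at least 100 p-values in (0, 1].
#' @return An object of class `bum_fit`: list with `lambda`, `a`,
#'   `log_lik`, `n_pvalues`, `pi_upper` (the upper bound
#'   `lambda + (1 - lambda) * a` on the noise mass).
#' @export
fit_bum <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("all p-values must lie in (0, 1]", call. = FALSE)
  if (length(p) < 100L)
    stop("need at least 100 p-values for a stable mixture fit", call. = FALSE)
  eps <- 1e-5
  lp <- log(p)
  negll <- function(par) {
    lam <- par[1]; a <- par[2]
    -sum(log(lam + (1 - lam) * a * exp((a - 1) * lp)))
  }
  best <- NULL
  for (lam0 in c(0.3, 0.5, 0.7, 0.9)) {
    for (a0 in c(0.1, 0.3, 0.5, 0.7)) {
      fit <- tryCatch(
        optim(c(lam0, a0), negll, method = "L-BFGS-B",
              lower = c(eps, eps), upper = c(1 - eps, 1 - eps)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
  }
  if (is.null(best)) stop("BUM optimization failed from every start",
                          call. = FALSE)
  lam <- best$par[1]; a <- best$par[2]
  structure(list(lambda = lam, a = a, log_lik = -best$value,
                 n_pvalues = length(p),
                 pi_upper = lam + (1 - lam) * a),
            class = "bum_fit")
}

#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf("Beta-uniform mixture fit: lambda = %.4f, a = %.4f (n = %d, logLik = %.2f)\n",
              x$lambda, x$a, x$n_pvalues, x$log_lik))
  cat(sprintf("  estimated noise mass upper bound pi = %.4f\n", x$pi_upper))
  invisible(x)
}

#' BUM p-value threshold at a target false discovery rate
#'
#' `tau(fdr) = ((pi - fdr * lambda) / (fdr * (1 - lambda)))^(1 / (a - 1))`
#' with `pi = lambda + (1 - lambda) * a`; p-values below tau are
#' signal-like at the requested FDR.
#'
#' @param fit a [fit_bum()] object.
#' @param fdr target FDR in (0, 1).
#' @return The threshold tau in (0, 1).
#' @export
bum_threshold <- function(fit, fdr) {
  stopifnot(inherits(fit, "bum_fit"))
  if (!is.numeric(fdr) || length(fdr) != 1L || fdr <= 0 || fdr >= 1)
    stop("'fdr' must be in (0, 1)", call. = FALSE)
  num <- fit$pi_upper - fdr * fit$lambda
  if (num <= 0)
    stop("degenerate threshold (pi <= fdr * lambda); use a larger fdr",
         call. = FALSE)
  log_ratio <- log(num) - log(fdr * (1 - fit$lambda))
  tau <- exp(log_ratio / (fit$a - 1))
  min(max(tau, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Additive node scores from a BUM fit
#'
#' Converts p-values to additive scores
#' `S(p) = (a - 1) * (log(p) - log(tau))` where `tau` is the FDR
#' threshold from [bum_threshold()]. Since `a < 1`, genes with `p < tau`
#' score positive and genes with `p > tau` negative; `S(tau) = 0`. The
#' score is computed on the log scale so extreme thresholds cannot
#' underflow.
#'
#' @param p_values named vector of per-gene p-values in (0, 1].
#' @param fit a [fit_bum()] object.
#' @param fdr target FDR in (0, 1) (the reference analysis uses a
#'   restrictive 0.001).
#' @return Named numeric vector of node scores.
#' @export
node_scores <- function(p_values, fit, fdr = 0.001) {
  stopifnot(inherits(fit, "bum_fit"))
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("all p-values must lie in (0, 1]", call. = FALSE)
  num <- fit$pi_upper - fdr * fit$lambda
  if (fdr <= 0 || fdr >= 1)
    stop("'fdr' must be in (0, 1)", call. = FALSE)
  if (num <= 0)
    stop("degenerate threshold (pi <= fdr * lambda); use a larger fdr",
         call. = FALSE)
  # (a-1)*log(tau) = log((pi - fdr*lambda)/(fdr*(1-lambda))), so work in logs
  log_tau_term <- log(num) - log(fdr * (1 - fit$lambda))
  setNames((fit$a - 1) * log(p) - log_tau_term, names(p_values))
}
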