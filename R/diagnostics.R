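## Convergence and precision diagnostics: rank-normalized split-chain R-hat
## and effective sample size, the R-hat < 1.1 convergence rule, and the
## ESS-cutoff precision flags.

split_chains <- function(x) {
  ## x: iterations x chains -> iterations/2 x 2*chains
  n <- nrow(x)
  h <- n %/% 2
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  matrix(qnorm((r - 3 / 8) / (length(x) + 1 / 4)), nrow(x), ncol(x))
}

rhat_core <- function(x) {
  ## classic potential scale reduction on an iterations x chains matrix
  n <- nrow(x); m <- ncol(x)
  mu_j <- colMeans(x)
  var_j <- apply(x, 2, var)
  W <- mean(var_j)
  B <- n * var(mu_j)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split-chain R-hat
#'
#' Splits each chain in half, rank-normalizes jointly, and returns the larger
#' of the bulk and tail (folded) potential scale reduction factors. Constant
#' parameters return 1.
#'
#' @param x iterations x chains matrix of draws for one parameter.
#' @return Scalar R-hat.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (all(abs(x - x[1]) < 1e-12)) return(1)
  xs <- split_chains(x)
  bulk <- rhat_core(rank_normalize(xs))
  folded <- rhat_core(rank_normalize(abs(xs - median(xs))))
  max(bulk, folded)
}

#' Bulk effective sample size
#'
#' Rank-normalized split-chain effective sample size using the
#' variogram-based combined autocorrelation estimate with Geyer's initial
#' monotone positive sequence.
#'
#' @param x iterations x chains matrix of draws for one parameter.
#' @return Scalar ESS (capped below the total draw count times log10 scale
#'   conventions are not applied).
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  if (all(abs(x - x[1]) < 1e-12)) return(length(x))
  z <- rank_normalize(split_chains(x))
  n <- nrow(z); m <- ncol(z)
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(z[, j], lag.max = n - 1, plot = FALSE, type = "covariance")$acf[, 1, 1]
    a * (n - 1) / n
  })
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n + var(colMeans(z))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  ## Geyer: sum consecutive pairs while positive, enforce monotonicity
  tau <- 0; t <- 1
  rho_prev <- Inf
  while (t + 1 <= n) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, rho_prev)
    rho_prev <- pair
    tau <- tau + pair
    t <- t + 2
  }
  tau <- max(2 * tau - 1, 1 / log10(n * m + 10))  # -1: lag-0 counted twice
  min(n * m / tau, n * m)
}

#' Convergence and precision diagnostics for a set of draws
#'
#' Computes R-hat and ESS per monitored parameter, the overall convergence
#' flag (all R-hat below 1.1), and precision flags at the ESS cutoffs 100,
#' 400 and 1000.
#'
#' @param draws array `iterations x chains x parameters`.
#' @param par_names optional parameter names.
#' @param divergences per-chain divergence counts.
#' @param ess_cutoffs precision cutoffs.
#' @return Object of class `"msar_diagnostics"`.
#' @export
diagnose_draws <- function(draws, par_names = NULL, divergences = 0,
                           ess_cutoffs = c(100, 400, 1000)) {
  np <- dim(draws)[3]
  if (is.null(par_names)) par_names <- paste0("par", seq_len(np))
  rh <- vapply(seq_len(np), function(j) rhat(draws[, , j]), numeric(1))
  es <- vapply(seq_len(np), function(j) ess_bulk(draws[, , j]), numeric(1))
  names(rh) <- names(es) <- par_names
  conv <- all(rh < 1.1)
  prec <- vapply(ess_cutoffs, function(x) all(es > x), logical(1))
  names(prec) <- paste0("ess", ess_cutoffs)
  structure(list(rhat = rh, ess = es,
                 divergence_count = sum(divergences),
                 converged = conv, precision = prec,
                 ess_cutoffs = ess_cutoffs),
            class = "msar_diagnostics")
}

#' @export
print.msar_diagnostics <- function(x, ...) {
  cat(sprintf("max R-hat = %.3f (%s); min ESS = %.0f; divergences = %d\n",
              max(x$rhat), if (x$converged) "converged" else "NOT converged",
              min(x$ess), x$divergence_count))
  cat("precision:",
      paste(sprintf("ESS>%d: %s", x$ess_cutoffs, ifelse(x$precision, "yes", "no")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Convergence and precision rates over replications
#'
#' Fraction of replications in which every parameter satisfied
#' R-hat < 1.1, and, per ESS cutoff, the fraction in which every parameter
#' exceeded the cutoff. Downstream metrics are computed over the converged
#' replications only.
#'
#' @param diag_list list of `"msar_diagnostics"` objects (one per
#'   replication).
#' @return List with `convergence_rate`, `precision_rates`, `M` (number of
#'   replications) and `converged` (logical vector).
#' @export
convergence_and_precision <- function(diag_list) {
  conv <- vapply(diag_list, function(d) d$converged, logical(1))
  cuts <- diag_list[[1]]$ess_cutoffs
  prec <- sapply(seq_along(cuts), function(j) {
    mean(vapply(diag_list, function(d) d$precision[j], logical(1)))
  })
  names(prec) <- paste0("ess", cuts)
  list(convergence_rate = mean(conv), precision_rates = prec,
       M = length(diag_list), converged = conv)
}
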