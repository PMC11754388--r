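## Hamilton forward filter: marginalizes the discrete state chain out of the
## MSAR(1) likelihood so that the posterior is differentiable. The recursion is
## initialized at xi_{1,i1} = 1, xi_{2,i1} = 0 (every individual starts in
## state 1) and the likelihood conditions on the first occasion: the sum of
## predictive log-densities runs over t = 2..T.

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[m == -Inf] <- -Inf
  out
}

#' Forward-filter log-likelihood of a two-state MSAR(1) panel
#'
#' Runs the Hamilton filter per individual: at each occasion the one-step
#' predictive density mixes the two state-conditional densities with the
#' chain-predicted state probabilities, the log-likelihood accumulates the
#' predictive log-densities (from `t = 2`, conditioning on the first
#' occasion), and the filtered probabilities are updated by Bayes' rule.
#' All accumulation is in log space.
#'
#' @param data a [panel_dataset()].
#' @param w a [within_params()] object.
#' @param b a [between_params()] object.
#' @param eps0 vector of individual random intercepts (length `N`).
#' @param include_mu1,include_mu2 include the time-varying predictor
#'   components in the transition probabilities.
#' @return An object of class `"msar_filter"`: list with `loglik`, `xi`
#'   (`N x T x 2` filtered probabilities), and `per_time_loglik` (`N x T`,
#'   first column `NA` by the conditioning convention).
#' @export
forward_loglik <- function(data, w, b, eps0,
                           include_mu1 = FALSE, include_mu2 = FALSE) {
  stopifnot(inherits(data, "msar_panel"))
  N <- data$N; Tn <- data$T; K <- data$K
  eta_tilde <- transition_predictor(data, b, eps0, include_mu1, include_mu2)
  p21 <- b$p21
  xi <- array(NA_real_, c(N, Tn, 2))
  xi[, 1, 1] <- 1; xi[, 1, 2] <- 0
  ptl <- matrix(NA_real_, N, Tn)
  zmat <- if (is.null(data$eta_z)) matrix(0, N, Tn) else data$eta_z
  for (i in seq_len(N)) {
    lxi <- c(0, -Inf)  # log filtered probabilities at t-1
    for (t in 2:Tn) {
      p11 <- stay_probability(eta_tilde[i, t])
      ## chain-predicted (one-step-ahead) state probabilities, in log space
      la1 <- logsumexp2(lxi[1] + log(p11), lxi[2] + log(p21))
      la2 <- logsumexp2(lxi[1] + log1p(-p11), lxi[2] + log1p(-p21))
      lf1 <- state_conditional_logdensity(data$eta_y[i, t, ], data$eta_y[i, t - 1, ],
                                          zmat[i, t], 1, w)
      lf2 <- state_conditional_logdensity(data$eta_y[i, t, ], data$eta_y[i, t - 1, ],
                                          zmat[i, t], 2, w)
      lt <- logsumexp2(la1 + lf1, la2 + lf2)
      if (!is.finite(lt)) {
        stop(sprintf("forward_loglik: non-finite predictive density at (i = %d, t = %d)",
                     i, t), call. = FALSE)
      }
      ptl[i, t] <- lt
      lxi <- c(la1 + lf1 - lt, la2 + lf2 - lt)
      xi[i, t, ] <- exp(lxi)
    }
  }
  structure(list(loglik = sum(ptl[, -1, drop = FALSE]),
                 xi = xi, per_time_loglik = ptl),
            class = "msar_filter")
}

#' Filtered state probabilities
#'
#' Extracts the `N x T x 2` array of filtered probabilities
#' \eqn{\xi_{sit} = P(S_{it} = s \mid \eta_{y,i,1:t})} from a filter result.
#'
#' @param fr an `"msar_filter"` object from [forward_loglik()].
#' @return `N x T x 2` array; each `(i, t)` slice sums to 1 and the first
#'   occasion is `(1, 0)`.
#' @export
filtered_probabilities <- function(fr) {
  stopifnot(inherits(fr, "msar_filter"))
  fr$xi
}

#' Brute-force path-enumeration log-likelihood (test oracle)
#'
#' Sums, over all \eqn{2^{T-1}} state paths starting in state 1, the product
#' of transition probabilities and state-conditional densities, in log space.
#' Exponential cost; refuses `T > 15`. Exists solely as an independent check
#' of [forward_loglik()].
#'
#' @inheritParams forward_loglik
#' @return Scalar log-likelihood (conditioning on the first occasion, as the
#'   filter does).
#' @export
brute_force_loglik <- function(data, w, b, eps0,
                               include_mu1 = FALSE, include_mu2 = FALSE) {
  stopifnot(inherits(data, "msar_panel"))
  Tn <- data$T
  if (Tn > 15L) {
    stop("brute_force_loglik: refusing T = ", Tn,
         " (> 15; cost grows as 2^(T-1) paths per individual)", call. = FALSE)
  }
  eta_tilde <- transition_predictor(data, b, eps0, include_mu1, include_mu2)
  p21 <- b$p21
  zmat <- if (is.null(data$eta_z)) matrix(0, data$N, Tn) else data$eta_z
  total <- 0
  npaths <- 2L^(Tn - 1L)
  ## all state paths with S_1 = 1, one row per path
  paths <- matrix(1L, npaths, Tn)
  if (Tn > 1L) {
    paths[, -1] <- 1L + as.matrix(expand.grid(
      rep(list(0:1), Tn - 1L)))[, , drop = FALSE]
  }
  for (i in seq_len(data$N)) {
    ## per-time state-conditional log-densities and log transition matrices
    lf <- matrix(NA_real_, Tn, 2)
    logP <- vector("list", Tn)
    for (t in 2:Tn) {
      for (s in 1:2) {
        lf[t, s] <- state_conditional_logdensity(
          data$eta_y[i, t, ], data$eta_y[i, t - 1, ], zmat[i, t], s, w)
      }
      logP[[t]] <- log(transition_matrix(stay_probability(eta_tilde[i, t]), p21))
    }
    path_l <- numeric(npaths)
    for (t in 2:Tn) {
      path_l <- path_l + logP[[t]][cbind(paths[, t - 1L], paths[, t])] +
        lf[t, paths[, t]]
    }
    m <- max(path_l)
    total <- total + m + log(sum(exp(path_l - m)))
  }
  total
}
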