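## Data generators reproducing the two simulation designs: time-invariant
## transition probabilities over an N x T x P x zero-rate grid, and
## time-varying transitions with cross-level interactions at N = 100.

## run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Alternating "nearly black" coefficient vector
#'
#' Builds the true slope vector used by the time-invariant design: the first
#' `floor(P * (1 - zero_rate))` entries alternate between +0.5 and -0.5 and
#' the remainder are exactly zero.
#'
#' @param P number of slopes.
#' @param zero_rate fraction of zero coefficients in `[0, 1)`.
#' @return Numeric vector of length `P`.
#' @export
make_beta_star <- function(P, zero_rate = 0.5) {
  if (P <= 0) stop("make_beta_star: P must be positive", call. = FALSE)
  if (zero_rate < 0 || zero_rate >= 1) {
    stop("make_beta_star: zero_rate must lie in [0, 1)", call. = FALSE)
  }
  n_nonzero <- floor(P * (1 - zero_rate))
  beta <- numeric(P)
  if (n_nonzero > 0) {
    beta[seq_len(n_nonzero)] <- 0.5 * (-1)^(seq_len(n_nonzero) - 1)
  }
  beta
}

#' Design of the time-invariant simulation study
#'
#' Fixed population values: \eqn{\beta_0 = 3}, covariate correlations 0.3 with
#' unit variances, \eqn{A_2 = 3}, \eqn{B_2 = 0.8}, \eqn{\gamma = 0.5},
#' \eqn{\sigma_\epsilon = 0.25}, return probability 0.05, and random-intercept
#' SD \eqn{\sigma_{\epsilon_0} = 1}. The study grid varies
#' `N` in \{50, 75, 100\}, `T` in \{10, 25, 50\}, `P` in \{5, 15, 25\} and the
#' zero rate in \{0.5, 0.75\}; any positive values are accepted.
#'
#' @param N,T,P sample sizes and number of between-level predictors.
#' @param zero_rate fraction of zero slopes.
#' @param seed RNG seed for [generate_sim1()].
#' @return An object of class `"msar_design"` (kind `"sim1"`).
#' @export
sim1_design <- function(N = 100, T = 50, P = 5, zero_rate = 0.5, seed = 1) {
  stopifnot(N > 0, T > 1, P > 0)
  structure(list(kind = "sim1", N = N, T = T, P = P, zero_rate = zero_rate,
                 seed = seed,
                 beta0 = 3, phi_offdiag = 0.3, A2 = 3, B2 = 0.8,
                 gamma = 0.5, sigma_eps = 0.25, sigma_eps0 = 1, p21 = 0.05),
            class = "msar_design")
}

#' Design of the time-varying simulation study
#'
#' `N = 100` individuals, `T` between 30 and 70, and `P = 15` predictors:
#' seven time-invariant slopes \eqn{\beta_x = (0.5, -0.5, 0.5, 0, 0, 0, 0)},
#' one time-varying slope \eqn{\beta_z = 0.5}, and seven cross-level
#' interaction slopes with non-zeros \eqn{(0.5, -0.5, 0.5)} placed in the last
#' three slots. Remaining population values as in [sim1_design()].
#'
#' @param N,T sample sizes.
#' @param seed RNG seed for [generate_sim2()].
#' @return An object of class `"msar_design"` (kind `"sim2"`).
#' @export
sim2_design <- function(N = 100, T = 50, seed = 1) {
  stopifnot(N > 0, T > 1)
  beta_x <- c(0.5, -0.5, 0.5, 0, 0, 0, 0)
  beta_xz <- c(0, 0, 0, 0, 0.5, -0.5, 0.5)
  structure(list(kind = "sim2", N = N, T = T, P = 15, Q = 7, seed = seed,
                 beta0 = 3, phi_offdiag = 0.3, A2 = 3, B2 = 0.8,
                 gamma = 0.5, sigma_eps = 0.25, sigma_eps0 = 1, p21 = 0.05,
                 beta_x = beta_x, beta_z = 0.5, beta_xz = beta_xz),
            class = "msar_design")
}

#' @export
print.msar_design <- function(x, ...) {
  cat(sprintf("MSAR simulation design (%s): N = %d, T = %d, P = %d",
              x$kind, x$N, x$T, x$P))
  if (x$kind == "sim1") cat(sprintf(", zero rate = %g", x$zero_rate))
  cat(sprintf(", seed = %d\n", x$seed))
  invisible(x)
}

## equicorrelation covariance used for the between-level covariates
equicorr <- function(Q, rho) {
  M <- matrix(rho, Q, Q); diag(M) <- 1; M
}

## shared generating core: given per-(i,t) transition predictors, simulate the
## chain and the within-level series
simulate_chain_and_series <- function(eta_tilde, design) {
  N <- nrow(eta_tilde); Tn <- ncol(eta_tilde)
  states <- matrix(1L, N, Tn)
  for (t in 2:Tn) {
    p11 <- stay_probability(eta_tilde[, t])
    u <- runif(N)
    prev <- states[, t - 1L]
    stay1 <- prev == 1L & u < p11
    back1 <- prev == 2L & u < design$p21
    states[, t] <- ifelse(prev == 1L, ifelse(stay1, 1L, 2L),
                          ifelse(back1, 1L, 2L))
  }
  eta_z <- matrix(rnorm(N * Tn), N, Tn)
  eta_y <- matrix(NA_real_, N, Tn)
  ## t = 1 from the state-1 model with eta_y(i,0) := 0
  eta_y[, 1] <- design$gamma * eta_z[, 1] + rnorm(N, 0, design$sigma_eps)
  for (t in 2:Tn) {
    s2 <- states[, t] == 2L
    mu <- ifelse(s2, design$A2 + design$B2 * eta_y[, t - 1L], 0) +
      design$gamma * eta_z[, t]
    eta_y[, t] <- mu + rnorm(N, 0, design$sigma_eps)
  }
  list(states = states, eta_y = eta_y, eta_z = eta_z)
}

#' Generate a dataset with time-invariant transition probabilities
#'
#' Draws between-level covariates from a multivariate normal with unit
#' variances and 0.3 correlations, individual random intercepts, a two-state
#' chain started in state 1 with stay probability
#' \eqn{\mathrm{logistic}(\mu_{0i})} and fixed return probability 0.05, and
#' the univariate within-level series under the design's population values.
#' Loadings are 1 and measurement errors 0, so the observed items equal the
#' latent variables.
#'
#' @param design a [sim1_design()].
#' @return An object of classes `"msar_sim"` and `"msar_panel"`, carrying the
#'   generating truth (`true_beta_star`, `true_eps0`, true states) and a
#'   design echo.
#' @export
generate_sim1 <- function(design = sim1_design()) {
  stopifnot(inherits(design, "msar_design"), design$kind == "sim1")
  with_seed(design$seed, {
    N <- design$N; Tn <- design$T; P <- design$P
    beta_star <- make_beta_star(P, design$zero_rate)
    Phi <- equicorr(P, design$phi_offdiag)
    eta_x <- matrix(rnorm(N * P), N, P) %*% chol(Phi)
    eps0 <- rnorm(N, 0, design$sigma_eps0)
    mu0 <- compute_mu0(design$beta0, beta_star, eta_x, eps0)
    eta_tilde <- matrix(mu0, N, Tn)
    sim <- simulate_chain_and_series(eta_tilde, design)
    out <- panel_dataset(sim$eta_y, eta_x, eta_z = sim$eta_z,
                         states = sim$states)
    out$true_beta_star <- beta_star
    out$true_eps0 <- eps0
    out$design <- design
    class(out) <- c("msar_sim", class(out))
    out
  })
}

#' Generate a dataset with time-varying transition probabilities
#'
#' As [generate_sim1()], but the transition predictor gains the time-varying
#' component \eqn{\mu_{1it} = \beta_z \eta_{z,it} + (\beta_{xz}^\top
#' \eta_{x,i})\eta_{z,it}} with standard-normal \eqn{\eta_{z,it}}, so the
#' chain's stay probability changes from occasion to occasion. The slope
#' vector exposed to estimation stacks
#' \eqn{(\beta_x, \beta_z, \beta_{xz})}, `P = 15` in the shipped design.
#'
#' @param design a [sim2_design()].
#' @return An `"msar_sim"` dataset (see [generate_sim1()]).
#' @export
generate_sim2 <- function(design = sim2_design()) {
  stopifnot(inherits(design, "msar_design"), design$kind == "sim2")
  with_seed(design$seed, {
    N <- design$N; Tn <- design$T; Q <- design$Q
    Phi <- equicorr(Q, design$phi_offdiag)
    eta_x <- matrix(rnorm(N * Q), N, Q) %*% chol(Phi)
    eps0 <- rnorm(N, 0, design$sigma_eps0)
    mu0 <- compute_mu0(design$beta0, design$beta_x, eta_x, eps0)
    ## eta_z drives both the transition predictor and the within-level series
    eta_z <- matrix(rnorm(N * Tn), N, Tn)
    mu1 <- compute_mu1(design$beta_z, design$beta_xz, eta_z, eta_x)
    eta_tilde <- matrix(mu0, N, Tn) + mu1
    ## chain and series share this eta_z
    states <- matrix(1L, N, Tn)
    for (t in 2:Tn) {
      p11 <- stay_probability(eta_tilde[, t])
      u <- runif(N)
      prev <- states[, t - 1L]
      states[, t] <- ifelse(prev == 1L, ifelse(u < p11, 1L, 2L),
                            ifelse(u < design$p21, 1L, 2L))
    }
    eta_y <- matrix(NA_real_, N, Tn)
    eta_y[, 1] <- design$gamma * eta_z[, 1] + rnorm(N, 0, design$sigma_eps)
    for (t in 2:Tn) {
      s2 <- states[, t] == 2L
      mu <- ifelse(s2, design$A2 + design$B2 * eta_y[, t - 1L], 0) +
        design$gamma * eta_z[, t]
      eta_y[, t] <- mu + rnorm(N, 0, design$sigma_eps)
    }
    out <- panel_dataset(eta_y, eta_x, eta_z = eta_z, states = states)
    out$true_beta_star <- c(design$beta_x, design$beta_z, design$beta_xz)
    out$true_eps0 <- eps0
    out$design <- design
    class(out) <- c("msar_sim", class(out))
    out
  })
}

#' Signal-to-noise ratio of a transition-predictor design
#'
#' Computes \eqn{\mathrm{SNR} = \beta^{*\top} \Phi \beta^* /
#' (\sigma_0^2 + \sigma_s^2)}: the variance contributed by the predictors
#' over the total residual variance of the logistic transition predictor
#' (random-intercept variance plus the logistic residual variance
#' \eqn{\pi^2/3}).
#'
#' @param beta_star true slope vector.
#' @param Phi_full covariance matrix of the full predictor vector.
#' @param sigma0_sq random-intercept variance.
#' @param sigma_s_sq residual variance of the latent logistic scale.
#' @return Scalar SNR.
#' @export
compute_snr <- function(beta_star, Phi_full, sigma0_sq = 1,
                        sigma_s_sq = pi^2 / 3) {
  Phi_full <- as.matrix(Phi_full)
  if (length(beta_star) != nrow(Phi_full)) {
    stop("compute_snr: length(beta_star) = ", length(beta_star),
         " does not match dim(Phi_full) = ", nrow(Phi_full), call. = FALSE)
  }
  drop(crossprod(beta_star, Phi_full %*% beta_star)) / (sigma0_sq + sigma_s_sq)
}

#' Signal-to-noise ratio implied by a simulation design
#'
#' Builds the predictor covariance of the design (for the time-varying design
#' blockwise: the covariate block, a unit block for the time-varying
#' predictor, and the interaction block \eqn{\Phi \sigma_z^2}, with zero
#' cross-blocks) and calls [compute_snr()].
#'
#' @param design an `"msar_design"`.
#' @return Scalar SNR.
#' @export
design_snr <- function(design) {
  stopifnot(inherits(design, "msar_design"))
  if (design$kind == "sim1") {
    beta <- make_beta_star(design$P, design$zero_rate)
    Phi <- equicorr(design$P, design$phi_offdiag)
  } else {
    Q <- design$Q
    beta <- c(design$beta_x, design$beta_z, design$beta_xz)
    Phi <- matrix(0, design$P, design$P)
    Phi[1:Q, 1:Q] <- equicorr(Q, design$phi_offdiag)
    Phi[Q + 1, Q + 1] <- 1
    idx <- (Q + 2):(2 * Q + 1)
    Phi[idx, idx] <- equicorr(Q, design$phi_offdiag)  # sigma_z^2 = 1
  }
  compute_snr(beta, Phi, design$sigma_eps0^2, pi^2 / 3)
}
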