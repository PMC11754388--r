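## Joint log-posterior on an unconstrained parameterization.
##
## Transforms: positive parameters are sampled on the log scale with their
## Jacobians added; the random intercepts are non-centered
## (eps0 = sigma_eps0 * raw); the Lasso-family coefficients are non-centered
## Laplace draws scaled by sigma_eta / lambda; the horseshoe coefficients are
## non-centered normal draws scaled by lambda_tilde * tau. The reported
## prior densities are over the constrained variables.

## derivative helpers for the transform chain rules (d log density / d x)
dgrad_halfnormal <- function(x, sd) -x / sd^2
dgrad_halfcauchy <- function(x, scale) -2 * x / (scale^2 + x^2)
dgrad_halfstudent <- function(x, df, scale) {
  -(df + 1) * x / (df * scale^2 + x^2)
}
dgrad_invgamma <- function(x, shape, rate) -(shape + 1) / x + rate / x^2

#' Build the differentiable joint log-posterior of an MSAR(1) model
#'
#' Assembles log prior + forward-filter log-likelihood + the log-Jacobians of
#' the unconstrained transforms into a single function of the unconstrained
#' parameter vector, with its analytic gradient (the likelihood part is a
#' hand-derived reverse-mode pass through the Hamilton recursion). Only the
#' univariate (`K = 1`) latent series is supported here; the discrete states
#' never appear as parameters.
#'
#' @param data a [panel_dataset()] with `K = 1`.
#' @param prior an [msar_prior()] for the transition slopes.
#' @param include_mu1 include the time-varying covariate (and its cross-level
#'   interactions) in the transition predictor; requires `eta_z`.
#' @param include_mu2 include the lagged latent series (and its cross-level
#'   interactions) in the transition predictor.
#' @param p21 fixed return probability from state 2 to state 1.
#' @param likelihood set `FALSE` to drop the data term (prior-only sampling,
#'   used for prior predictive checks).
#' @return An object of class `"msar_posterior"`: a list with `lp_grad(theta)`
#'   (returns `list(value, grad)`), `lp(theta)`, `n_par`, `P`, `unpack(theta)`
#'   (constrained parameter list), `natural(theta)` (named vector of
#'   natural-scale parameters for monitoring) and `init(n)` (random
#'   unconstrained starting values).
#' @export
build_log_posterior <- function(data, prior = msar_prior("ridge"),
                                include_mu1 = FALSE, include_mu2 = FALSE,
                                p21 = 0.05, likelihood = TRUE) {
  stopifnot(inherits(data, "msar_panel"), inherits(prior, "msar_prior"))
  if (data$K != 1L) {
    stop("build_log_posterior: only K = 1 models are supported by the sampler",
         call. = FALSE)
  }
  if (include_mu1 && is.null(data$eta_z)) {
    stop("build_log_posterior: include_mu1 = TRUE but the dataset has no eta_z",
         call. = FALSE)
  }
  N <- data$N; Tn <- data$T; Q <- data$Q
  P <- Q + if (include_mu1) 1L + Q else 0L
  P <- P + if (include_mu2) 1L + Q else 0L
  y <- matrix(data$eta_y[, , 1], N, Tn)
  z <- if (is.null(data$eta_z)) matrix(0, N, Tn) else data$eta_z
  X <- data$eta_x
  Xt <- t(X)
  ylag <- cbind(0, y[, -Tn, drop = FALSE])
  family <- prior$family
  linked <- identical(prior$sigma_eta, "sigma_eps0")
  se_fixed <- if (linked) NA_real_ else
    if (family == "reg_hs") NA_real_ else prior$sigma_eta
  tau0 <- if (family == "reg_hs") resolve_tau0(prior, N, Tn) else NA_real_

  ## ---- index map ----------------------------------------------------------
  i_b0 <- 1L; i_A2 <- 2L; i_B2 <- 3L; i_g <- 4L; i_s <- 5L; i_s0 <- 6L
  i_e0 <- 6L + seq_len(N)
  base <- 6L + N
  fam_idx <- switch(family,
    ridge = list(beta = base + seq_len(P)),
    blasso = list(b = base + seq_len(P), u_lam = base + P + 1L),
    abss_lasso = list(b = base + seq_len(P), v = base + P + seq_len(P),
                      u_lam = base + 2L * P + seq_len(P)),
    reg_hs = list(zr = base + seq_len(P), u_lam = base + P + seq_len(P),
                  u_tau = base + 2L * P + 1L, u_c2 = base + 2L * P + 2L))
  n_par <- max(unlist(fam_idx))

  beta_names <- paste0("beta[", seq_len(P), "]")
  nat_names <- c(beta_names, "beta0", "A2", "B2", "gamma",
                 "sigma_eps", "sigma_eps0",
                 paste0("eps0[", seq_len(N), "]"),
                 switch(family,
                        ridge = character(0),
                        blasso = "lambda",
                        abss_lasso = c(paste0("nu[", seq_len(P), "]"),
                                       paste0("lambda[", seq_len(P), "]")),
                        reg_hs = c(paste0("lambda[", seq_len(P), "]"),
                                   "tau", "c2")))

  unpack <- function(theta) {
    beta0 <- exp(theta[i_b0]); A2 <- exp(theta[i_A2])
    B2 <- theta[i_B2]; gam <- theta[i_g]
    sig <- exp(theta[i_s]); sig0 <- exp(theta[i_s0])
    r0 <- theta[i_e0]; eps0 <- sig0 * r0
    out <- list(beta0 = beta0, A2 = A2, B2 = B2, gamma = gam,
                sigma_eps = sig, sigma_eps0 = sig0, eps0 = eps0)
    se <- if (linked) sig0 else se_fixed
    if (family == "ridge") {
      out$beta <- theta[fam_idx$beta]
    } else if (family == "blasso") {
      out$lambda <- exp(theta[fam_idx$u_lam])
      out$beta <- theta[fam_idx$b] * se / out$lambda
    } else if (family == "abss_lasso") {
      out$nu <- plogis(theta[fam_idx$v])
      out$lambda_p <- exp(theta[fam_idx$u_lam])
      out$beta_bar <- theta[fam_idx$b] * se / out$lambda_p
      out$beta <- out$beta_bar * out$nu
    } else {
      out$lambda_p <- exp(theta[fam_idx$u_lam])
      out$tau <- exp(theta[fam_idx$u_tau])
      out$c2 <- exp(theta[fam_idx$u_c2])
      lt <- hs_lambda_tilde(out$lambda_p, out$tau, out$c2)
      out$beta <- theta[fam_idx$zr] * lt * out$tau
    }
    out
  }

  split_beta <- function(beta) {
    bx <- beta[seq_len(Q)]; off <- Q
    bz <- 0; bxz <- numeric(Q); by <- 0; bxy <- numeric(Q)
    if (include_mu1) {
      bz <- beta[off + 1L]; bxz <- beta[off + 1L + seq_len(Q)]; off <- off + 1L + Q
    }
    if (include_mu2) {
      by <- beta[off + 1L]; bxy <- beta[off + 1L + seq_len(Q)]
    }
    list(bx = bx, bz = bz, bxz = bxz, by = by, bxy = bxy)
  }

  reject <- function() list(value = -Inf, grad = numeric(n_par))

  lp_grad <- function(theta) {
    if (any(!is.finite(theta))) return(reject())
    pl <- unpack(theta)
    if (any(!vapply(pl, function(v) all(is.finite(v)), logical(1)))) {
      return(reject())
    }
    g <- numeric(n_par)
    bb <- split_beta(pl$beta)

    ## transition predictor; time-invariant models pass it as one column and
    ## get the per-individual eta-gradient back directly
    tinv <- !include_mu1 && !include_mu2
    mu0 <- pl$beta0 + drop(X %*% bb$bx) + pl$eps0
    if (tinv) {
      eta <- matrix(mu0, N, 1)
    } else {
      eta <- matrix(mu0, N, Tn)
      if (include_mu1) eta <- eta + z * (bb$bz + drop(X %*% bb$bxz))
      if (include_mu2) eta <- eta + ylag * (bb$by + drop(X %*% bb$bxy))
    }

    if (likelihood) {
      fl <- msar_filter_cpp(y, z, eta, pl$A2, pl$B2, pl$gamma, pl$sigma_eps,
                            p21, TRUE, FALSE)
      if (!is.finite(fl$loglik)) return(reject())
      lp <- fl$loglik
      d_eta <- fl$d_eta
      s_i <- if (tinv) d_eta[, 1] else rowSums(d_eta)
    } else {
      fl <- list(loglik = 0, dA2 = 0, dB2 = 0, dgamma = 0, dsigma = 0)
      d_eta <- matrix(0, N, if (tinv) 1 else Tn)
      s_i <- numeric(N)
      lp <- 0
    }

    ## dL/dbeta on the natural scale
    gbeta <- numeric(P)
    gbeta[seq_len(Q)] <- drop(Xt %*% s_i)
    off <- Q
    if (include_mu1) {
      dz <- d_eta * z
      gbeta[off + 1L] <- sum(dz)
      gbeta[off + 1L + seq_len(Q)] <- drop(Xt %*% rowSums(dz))
      off <- off + 1L + Q
    }
    if (include_mu2) {
      dy <- d_eta * ylag
      gbeta[off + 1L] <- sum(dy)
      gbeta[off + 1L + seq_len(Q)] <- drop(Xt %*% rowSums(dy))
    }

    ## baseline priors + transforms
    lp <- lp + dhalfnormal_log(pl$beta0, 10) + theta[i_b0] +
      dhalfnormal_log(pl$A2, 10) + theta[i_A2] +
      dnorm(pl$B2, 0, 1, log = TRUE) +
      dnorm(pl$gamma, 0, 1, log = TRUE) +
      dhalfcauchy_log(pl$sigma_eps, 2.5) + theta[i_s] +
      dhalfcauchy_log(pl$sigma_eps0, 2.5) + theta[i_s0] +
      sum(dnorm(theta[i_e0], 0, 1, log = TRUE))

    g[i_b0] <- (sum(s_i) + dgrad_halfnormal(pl$beta0, 10)) * pl$beta0 + 1
    g[i_A2] <- (fl$dA2 + dgrad_halfnormal(pl$A2, 10)) * pl$A2 + 1
    g[i_B2] <- fl$dB2 - pl$B2
    g[i_g] <- fl$dgamma - pl$gamma
    g[i_s] <- (fl$dsigma + dgrad_halfcauchy(pl$sigma_eps, 2.5)) * pl$sigma_eps + 1
    g[i_s0] <- (sum(s_i * theta[i_e0]) +
                  dgrad_halfcauchy(pl$sigma_eps0, 2.5)) * pl$sigma_eps0 + 1
    g[i_e0] <- s_i * pl$sigma_eps0 - theta[i_e0]

    ## slope prior block
    if (family == "ridge") {
      sdv <- se_fixed / sqrt(prior$lambda_fixed)
      lp <- lp + sum(dnorm(pl$beta, 0, sdv, log = TRUE))
      g[fam_idx$beta] <- gbeta - pl$beta / sdv^2
    } else if (family == "blasso") {
      se <- if (linked) pl$sigma_eps0 else se_fixed
      braw <- theta[fam_idx$b]
      lp <- lp + sum(dlaplace_log(braw, 1)) +
        dhalfcauchy_log(pl$lambda, prior$a_lambda) + theta[fam_idx$u_lam]
      g[fam_idx$b] <- gbeta * se / pl$lambda - sign(braw)
      g[fam_idx$u_lam] <- -sum(gbeta * pl$beta) +
        dgrad_halfcauchy(pl$lambda, prior$a_lambda) * pl$lambda + 1
      if (linked) g[i_s0] <- g[i_s0] + sum(gbeta * pl$beta)
    } else if (family == "abss_lasso") {
      se <- if (linked) pl$sigma_eps0 else se_fixed
      braw <- theta[fam_idx$b]; v <- theta[fam_idx$v]
      nu <- pl$nu; lam <- pl$lambda_p
      ## Beta prior on nu plus the logit Jacobian collapses to
      ## a*log(nu) + b*log(1-nu) - log B(a, b)
      lp <- lp + sum(dlaplace_log(braw, 1)) +
        prior$beta_a * sum(log(nu)) + prior$beta_b * sum(log1p(-nu)) -
        P * lbeta(prior$beta_a, prior$beta_b) +
        sum(dhalfcauchy_log(lam, prior$a_lambda)) + sum(theta[fam_idx$u_lam])
      g[fam_idx$b] <- gbeta * nu * se / lam - sign(braw)
      g[fam_idx$v] <- gbeta * pl$beta_bar * nu * (1 - nu) +
        prior$beta_a * (1 - nu) - prior$beta_b * nu
      g[fam_idx$u_lam] <- -gbeta * pl$beta +
        dgrad_halfcauchy(lam, prior$a_lambda) * lam + 1
      if (linked) g[i_s0] <- g[i_s0] + sum(gbeta * pl$beta)
    } else {  # regularized horseshoe
      zr <- theta[fam_idx$zr]
      lam <- pl$lambda_p; tau <- pl$tau; c2 <- pl$c2
      D <- c2 + tau^2 * lam^2
      g2 <- c2 * lam^2 / D          # lambda_tilde^2
      lt <- sqrt(g2)
      lp <- lp + sum(dnorm(zr, 0, 1, log = TRUE)) +
        sum(dhalfcauchy_log(lam, 1)) + sum(theta[fam_idx$u_lam]) +
        dhalfstudent_log(tau, prior$nu0, tau0) + theta[fam_idx$u_tau] +
        dinvgamma_log(c2, prior$nu_c / 2, prior$nu_c * prior$s_c2 / 2) +
        theta[fam_idx$u_c2]
      dg_dlam <- 2 * c2^2 * lam / D^2
      dg_dtau <- -2 * tau * lam^4 * c2 / D^2
      dg_dc2 <- tau^2 * lam^4 / D^2
      g[fam_idx$zr] <- gbeta * lt * tau - zr
      g[fam_idx$u_lam] <- gbeta * zr * tau * dg_dlam / (2 * lt) * lam +
        dgrad_halfcauchy(lam, 1) * lam + 1
      g[fam_idx$u_tau] <- sum(gbeta * (zr * lt + zr * tau * dg_dtau / (2 * lt))) * tau +
        dgrad_halfstudent(tau, prior$nu0, tau0) * tau + 1
      g[fam_idx$u_c2] <- sum(gbeta * zr * tau * dg_dc2 / (2 * lt)) * c2 +
        dgrad_invgamma(c2, prior$nu_c / 2, prior$nu_c * prior$s_c2 / 2) * c2 + 1
    }

    if (!is.finite(lp)) {
      return(list(value = -Inf, grad = g))
    }
    list(value = lp, grad = g)
  }

  natural <- function(theta) {
    pl <- unpack(theta)
    c(pl$beta, pl$beta0, pl$A2, pl$B2, pl$gamma, pl$sigma_eps, pl$sigma_eps0,
      pl$eps0,
      switch(family,
             ridge = numeric(0),
             blasso = pl$lambda,
             abss_lasso = c(pl$nu, pl$lambda_p),
             reg_hs = c(pl$lambda_p, pl$tau, pl$c2)))
  }

  init <- function() {
    th <- rnorm(n_par, 0, 0.3)
    th[i_b0] <- log(runif(1, 0.5, 2))
    th[i_A2] <- log(runif(1, 0.5, 2))
    th[i_s] <- log(runif(1, 0.3, 1.2))
    th[i_s0] <- log(runif(1, 0.5, 1.5))
    th
  }

  structure(list(
    lp_grad = lp_grad,
    lp = function(theta) lp_grad(theta)$value,
    unpack = unpack, natural = natural, init = init,
    n_par = n_par, P = P, N = N, T = Tn, Q = Q,
    nat_names = nat_names, family = family, prior = prior,
    include_mu1 = include_mu1, include_mu2 = include_mu2, p21 = p21
  ), class = "msar_posterior")
}
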