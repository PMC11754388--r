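#' Fit a two-level Markov-switching AR(1) model
#'
#' The main fitting function. Builds the marginalized log-posterior (the
#' discrete state chain is integrated out by the Hamilton forward filter, so
#' the posterior is differentiable), samples it with the built-in NUTS
#' sampler, and returns draws, convergence diagnostics and summaries.
#'
#' The model: conditional on the latent two-state chain \eqn{S_{it}}, the
#' univariate series follows
#' \eqn{\eta_{y,it} = A_s + B_s\eta_{y,it-1} + \gamma\eta_{z,it} +
#' \epsilon_{it}} with state-1 constraints \eqn{A_1 = B_1 = 0}; the chain
#' starts in state 1, stays there with probability
#' \eqn{\mathrm{logistic}(\tilde\eta_{it})} and returns from state 2 with
#' fixed probability `p21`. The transition predictor \eqn{\tilde\eta_{it}}
#' contains a random intercept with between-level covariates and, optionally,
#' a time-varying covariate with cross-level interactions
#' (`include_mu1`) and the lagged series with its interactions
#' (`include_mu2`). The slope vector \eqn{\beta^*} receives the regularizing
#' prior in `prior`; everything else gets weakly informative baseline priors.
#'
#' @param data a [panel_dataset()] (or simulated dataset) with `K = 1`.
#' @param prior an [msar_prior()] or preset name string (see
#'   [prior_preset()]).
#' @param include_mu1 include the time-varying covariate in the transition
#'   predictor (defaults to `TRUE` for datasets generated under the
#'   time-varying design).
#' @param include_mu2 include the lagged series in the transition predictor.
#' @param chains,iter,warmup,seed sampler settings (see [sampler_config()]).
#' @param control list overriding `target_accept`, `max_treedepth`,
#'   `step_size`, `brute_force`.
#' @param monitor_eps0 include the individual random intercepts among the
#'   monitored parameters (they always remain part of the sampled state).
#' @return An object of class `"msar_fit"`.
#' @examples
#' d <- generate_sim1(sim1_design(N = 20, T = 10, P = 5, seed = 1))
#' fit <- msar(d, prior = "Ridge-0", chains = 2, iter = 400, warmup = 200)
#' print(fit)
#' coef(fit)
#' @export
msar <- function(data, prior = msar_prior("ridge"),
                 include_mu1 = NULL, include_mu2 = FALSE,
                 chains = 4, iter = 2000, warmup = 1000, seed = 1,
                 control = list(), monitor_eps0 = TRUE) {
  if (is.character(prior)) prior <- prior_preset(prior)
  if (is.null(include_mu1)) {
    include_mu1 <- inherits(data, "msar_sim") &&
      identical(data$design$kind, "sim2")
  }
  post <- build_log_posterior(data, prior, include_mu1 = include_mu1,
                              include_mu2 = include_mu2)
  cfg <- sampler_config(chains = chains, iter = iter, warmup = warmup,
                        seed = seed,
                        target_accept = control$target_accept %||% 0.8,
                        max_treedepth = control$max_treedepth %||% 10,
                        step_size = control$step_size,
                        brute_force = isTRUE(control$brute_force))
  smp <- sample_posterior(post, cfg)

  ## map unconstrained draws to the natural scale
  keep <- dim(smp$draws)[1]
  n_nat <- length(post$nat_names)
  nat <- array(NA_real_, c(keep, cfg$chains, n_nat),
               dimnames = list(NULL, NULL, post$nat_names))
  for (ch in seq_len(cfg$chains)) {
    for (it in seq_len(keep)) {
      nat[it, ch, ] <- post$natural(smp$draws[it, ch, ])
    }
  }
  monitored <- post$nat_names
  if (!monitor_eps0) monitored <- grep("^eps0\\[", monitored,
                                       value = TRUE, invert = TRUE)
  diag <- diagnose_draws(nat[, , monitored, drop = FALSE], monitored,
                         divergences = smp$divergences)
  fit <- structure(list(
    draws = nat, udraws = smp$draws, posterior = post, prior = prior,
    data = data, config = cfg, divergences = smp$divergences,
    diagnostics = diag, monitored = monitored,
    include_mu1 = include_mu1, include_mu2 = include_mu2
  ), class = "msar_fit")
  fit$summary <- summarize(fit)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior summaries
#'
#' Mean, SD, and 95\% interval per monitored parameter. The interval is
#' equal-tailed by default; highest-posterior-density intervals are available
#' with `interval = "hpd"`.
#'
#' @param fit an `"msar_fit"` (or an iterations x chains x parameters array
#'   with named parameters).
#' @param interval `"equal"` or `"hpd"`.
#' @param prob interval mass.
#' @return `data.frame` with columns `mean`, `sd`, `lower`, `upper`, `rhat`,
#'   `ess` (diagnostics where available).
#' @export
summarize <- function(fit, interval = c("equal", "hpd"), prob = 0.95) {
  interval <- match.arg(interval)
  if (inherits(fit, "msar_fit")) {
    arr <- fit$draws
    diag <- fit$diagnostics
  } else {
    arr <- fit
    diag <- NULL
  }
  if (dim(arr)[1] * dim(arr)[2] < 4) {
    stop("summarize: too few draws for an interval", call. = FALSE)
  }
  pn <- dimnames(arr)[[3]]
  out <- data.frame(row.names = pn)
  flat <- matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3])
  out$mean <- colMeans(flat)
  out$sd <- apply(flat, 2, sd)
  if (interval == "equal") {
    qs <- apply(flat, 2, quantile, probs = c((1 - prob) / 2, 1 - (1 - prob) / 2))
    out$lower <- qs[1, ]; out$upper <- qs[2, ]
  } else {
    hp <- apply(flat, 2, hpd_interval, prob = prob)
    out$lower <- hp[1, ]; out$upper <- hp[2, ]
  }
  if (!is.null(diag)) {
    out$rhat <- diag$rhat[pn]
    out$ess <- diag$ess[pn]
  }
  out
}

## shortest interval containing `prob` of the draws
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1, floor(prob * n))
  widths <- x[(k + 1):n] - x[seq_len(n - k)]
  j <- which.min(widths)
  c(x[j], x[j + k])
}

#' Posterior mode (penalized point estimate)
#'
#' Maximizes the joint log-posterior over the unconstrained parameterization,
#' starting from the posterior mean of the draws, and returns the
#' natural-scale parameters at the optimum. Modes under the regularizing
#' priors correspond to the frequentist penalized estimates.
#'
#' @param fit an `"msar_fit"`.
#' @param maxit optimizer iteration cap.
#' @return Named vector of natural-scale parameters at the mode.
#' @export
posterior_mode <- function(fit, maxit = 500) {
  post <- fit$posterior
  flat <- matrix(fit$udraws, prod(dim(fit$udraws)[1:2]), dim(fit$udraws)[3])
  start <- colMeans(flat)
  opt <- optim(start, fn = function(th) -post$lp_grad(th)$value,
               gr = function(th) -post$lp_grad(th)$grad,
               method = "BFGS", control = list(maxit = maxit))
  setNames(post$natural(opt$par), post$nat_names)
}

## ---------------------------------------------------------------------------
## methods
## ---------------------------------------------------------------------------

#' @export
print.msar_fit <- function(x, ...) {
  cat("Two-level Markov-switching AR(1) fit\n")
  cat(sprintf("  data: N = %d, T = %d, P = %d transition slopes; prior: %s\n",
              x$posterior$N, x$posterior$T, x$posterior$P, x$prior$name))
  cat(sprintf("  sampler: %d chains x %d iterations (%d warmup); %d divergences\n",
              x$config$chains, x$config$iter, x$config$warmup,
              sum(x$divergences)))
  print(x$diagnostics)
  bn <- grep("^beta\\[", rownames(x$summary), value = TRUE)
  cat("\nTransition slopes (posterior mean [95% CI]):\n")
  s <- x$summary[bn, ]
  for (i in seq_along(bn)) {
    cat(sprintf("  %-10s % .3f [% .3f, % .3f]\n", bn[i],
                s$mean[i], s$lower[i], s$upper[i]))
  }
  invisible(x)
}

#' @export
summary.msar_fit <- function(object, interval = c("equal", "hpd"),
                             prob = 0.95, ...) {
  summarize(object, interval = match.arg(interval), prob = prob)
}

#' @export
coef.msar_fit <- function(object, ...) {
  s <- object$summary
  bn <- grep("^beta\\[", rownames(s), value = TRUE)
  setNames(s[bn, "mean"], bn)
}

#' One-step-ahead standardized residuals at the posterior mean
#'
#' Runs the forward filter at the posterior-mean parameters and returns
#' `(eta_y - E[eta_y | past]) / sd`, with the predictive mean mixing the two
#' state-conditional means by the chain-predicted state probabilities.
#'
#' @param object an `"msar_fit"`.
#' @param ... unused.
#' @return `N x T` matrix (first column `NA`: the filter conditions on the
#'   first occasion).
#' @export
residuals.msar_fit <- function(object, ...) {
  pm <- object$summary$mean
  names(pm) <- rownames(object$summary)
  post <- object$posterior
  d <- object$data
  N <- d$N; Tn <- d$T
  y <- matrix(d$eta_y[, , 1], N, Tn)
  z <- if (is.null(d$eta_z)) matrix(0, N, Tn) else d$eta_z
  beta <- pm[grep("^beta\\[", names(pm))]
  eps0 <- pm[grep("^eps0\\[", names(pm))]
  b <- between_from_beta(beta, post, pm["beta0"], pm["sigma_eps0"])
  eta <- transition_predictor(d, b, eps0,
                              include_mu1 = post$include_mu1,
                              include_mu2 = post$include_mu2)
  res <- matrix(NA_real_, N, Tn)
  fl <- msar_filter_cpp(y, z, eta, pm["A2"], pm["B2"], pm["gamma"],
                        pm["sigma_eps"], post$p21, FALSE, TRUE)
  xi1 <- fl$xi1
  for (t in 2:Tn) {
    p11 <- stay_probability(eta[, t])
    a1 <- xi1[, t - 1] * p11 + (1 - xi1[, t - 1]) * post$p21
    m1 <- pm["gamma"] * z[, t]
    m2 <- pm["A2"] + pm["B2"] * y[, t - 1] + pm["gamma"] * z[, t]
    mu <- a1 * m1 + (1 - a1) * m2
    v <- pm["sigma_eps"]^2 + a1 * (1 - a1) * (m2 - m1)^2
    res[, t] <- (y[, t] - mu) / sqrt(v)
  }
  res
}

## rebuild a between_params object from the monitored slope vector
between_from_beta <- function(beta, post, beta0, sigma_eps0) {
  Q <- post$Q
  bx <- beta[seq_len(Q)]; off <- Q
  bz <- 0; bxz <- numeric(Q); by <- numeric(0); bxy <- numeric(0)
  if (post$include_mu1) {
    bz <- beta[off + 1]; bxz <- beta[off + 1 + seq_len(Q)]; off <- off + 1 + Q
  }
  if (post$include_mu2) {
    by <- beta[off + 1]; bxy <- beta[off + 1 + seq_len(Q)]
  }
  between_params(beta0 = unname(beta0), beta_x = unname(bx), beta_z = unname(bz),
                 beta_xz = unname(bxz), beta_y = unname(by),
                 beta_xy = unname(bxy), sigma_eps0 = unname(sigma_eps0),
                 p21 = post$p21)
}

#' Filtered state probabilities at the posterior mean
#'
#' @param object an `"msar_fit"`.
#' @param ... unused.
#' @return `N x T` matrix of filtered probabilities of being in state 1.
#' @export
fitted.msar_fit <- function(object, ...) {
  pm <- object$summary$mean
  names(pm) <- rownames(object$summary)
  post <- object$posterior
  d <- object$data
  y <- matrix(d$eta_y[, , 1], d$N, d$T)
  z <- if (is.null(d$eta_z)) matrix(0, d$N, d$T) else d$eta_z
  beta <- pm[grep("^beta\\[", names(pm))]
  eps0 <- pm[grep("^eps0\\[", names(pm))]
  b <- between_from_beta(beta, post, pm["beta0"], pm["sigma_eps0"])
  eta <- transition_predictor(d, b, eps0, post$include_mu1, post$include_mu2)
  msar_filter_cpp(y, z, eta, pm["A2"], pm["B2"], pm["gamma"],
                  pm["sigma_eps"], post$p21, FALSE, TRUE)$xi1
}

#' Simulate replicate datasets from a fitted model
#'
#' Generates new panels from the generating equations at the posterior-mean
#' parameters (new covariates, random intercepts, states and series).
#'
#' @param object an `"msar_fit"`.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return List of `"msar_sim"` datasets.
#' @export
simulate.msar_fit <- function(object, nsim = 1, seed = 1, ...) {
  pm <- object$summary$mean
  names(pm) <- rownames(object$summary)
  post <- object$posterior
  lapply(seq_len(nsim), function(j) {
    des <- sim1_design(N = post$N, T = post$T, P = post$Q,
                       seed = seed + j - 1)
    des$beta0 <- unname(pm["beta0"]); des$A2 <- unname(pm["A2"])
    des$B2 <- unname(pm["B2"]); des$gamma <- unname(pm["gamma"])
    des$sigma_eps <- unname(pm["sigma_eps"])
    des$sigma_eps0 <- unname(pm["sigma_eps0"])
    d <- generate_sim1(des)
    d
  })
}

#' Plot method: slope intervals or traces
#'
#' `type = "intervals"` draws the posterior means and 95\% intervals of the
#' transition slopes (truth overlaid for simulated data); `type = "trace"`
#' draws per-chain trace plots for a few parameters.
#'
#' @param x an `"msar_fit"`.
#' @param type plot type.
#' @param pars parameters for the trace plot.
#' @param ... passed to the underlying plotting calls.
#' @importFrom graphics abline arrows axis legend lines matplot par points
#' @export
plot.msar_fit <- function(x, type = c("intervals", "trace"),
                          pars = NULL, ...) {
  type <- match.arg(type)
  if (type == "intervals") {
    s <- x$summary
    bn <- grep("^beta\\[", rownames(s), value = TRUE)
    idx <- seq_along(bn)
    plot(idx, s[bn, "mean"], ylim = range(s[bn, c("lower", "upper")]),
         pch = 19, xlab = "slope index", ylab = "posterior mean and 95% CI",
         main = paste("Transition slopes -", x$prior$name), xaxt = "n", ...)
    axis(1, at = idx)
    arrows(idx, s[bn, "lower"], idx, s[bn, "upper"],
           angle = 90, code = 3, length = 0.03)
    abline(h = 0, lty = 3)
    if (!is.null(x$data$true_beta_star)) {
      points(idx, x$data$true_beta_star, col = 2, pch = 4, cex = 1.2)
      legend("topright", legend = c("posterior", "truth"),
             pch = c(19, 4), col = c(1, 2), bty = "n")
    }
  } else {
    if (is.null(pars)) {
      pars <- intersect(c("beta[1]", "A2", "B2", "sigma_eps"),
                        dimnames(x$draws)[[3]])
    }
    op <- par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1.5, 1))
    on.exit(par(op))
    for (p in pars) {
      matplot(x$draws[, , p], type = "l", lty = 1, ylab = p, xlab = "")
    }
  }
  invisible(x)
}
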