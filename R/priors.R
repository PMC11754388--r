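## Regularizing priors for the transition-slope vector beta*, the named
## sensitivity presets, and the weakly informative baseline priors for all
## remaining parameters. All log-densities are over the constrained variables;
## the posterior builder adds the log-Jacobians of its unconstrained
## transforms separately.

## -- distribution helpers (log densities) -----------------------------------

dlaplace_log <- function(x, scale) -log(2 * scale) - abs(x) / scale

dhalfcauchy_log <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) + dcauchy(x, 0, scale, log = TRUE))
}

dhalfnormal_log <- function(x, sd) {
  ifelse(x < 0, -Inf, log(2) + dnorm(x, 0, sd, log = TRUE))
}

dhalfstudent_log <- function(x, df, scale) {
  ifelse(x < 0, -Inf,
         log(2) + stats::dt(x / scale, df = df, log = TRUE) - log(scale))
}

dinvgamma_log <- function(x, shape, rate) {
  ifelse(x <= 0, -Inf,
         shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x)
}

## LKJ correlation density, up to its normalizing constant (constant in the
## parameters, so sufficient for posterior work): (eta - 1) * log det(R).
dlkj_log_unnorm <- function(R, eta) {
  (eta - 1) * determinant(R, logarithm = TRUE)$modulus[1]
}

## -- PriorSpec ---------------------------------------------------------------

#' Specify a regularizing prior family for the transition slopes
#'
#' Four families are available for the slope vector \eqn{\beta^*} of the
#' transition-probability predictors:
#' \describe{
#'   \item{`ridge`}{\eqn{\beta_p \sim N(0, \sigma_\eta^2/\lambda)} with fixed
#'     penalty \eqn{\lambda}; the default (\eqn{\sigma_\eta = \lambda = 1}) is
#'     the standard normal.}
#'   \item{`blasso`}{Bayesian Lasso: \eqn{\beta_p \sim
#'     \mathrm{Laplace}(0, \sigma_\eta/\lambda)} with
#'     \eqn{\lambda \sim C^+(0, a_\lambda)}.}
#'   \item{`abss_lasso`}{adaptive Bayesian spike-and-slab Lasso:
#'     \eqn{\beta_p = \bar\beta_p \nu_p} with
#'     \eqn{\bar\beta_p \sim \mathrm{Laplace}(0, \sigma_\eta/\lambda_p)},
#'     \eqn{\nu_p \sim \mathrm{Beta}(a, b)} and
#'     \eqn{\lambda_p \sim C^+(0, a_\lambda)}.}
#'   \item{`reg_hs`}{regularized horseshoe:
#'     \eqn{\beta_p \sim N(0, \tilde\lambda_p^2 \tau^2)} with
#'     \eqn{\tilde\lambda_p^2 = c^2\lambda_p^2 / (c^2 + \tau^2\lambda_p^2)},
#'     \eqn{\lambda_p \sim C^+(0,1)},
#'     \eqn{\tau \sim t^+_{\nu_0}(0, \tau_0^2)} and
#'     \eqn{c^2 \sim I\Gamma(\nu_c/2, \nu_c s_c^2/2)}.}
#' }
#'
#' For the Lasso families, `sigma_eta = "sigma_eps0"` (the default) links the
#' Laplace scale to the model's random-intercept standard deviation; a fixed
#' numeric value may be supplied instead. For the regularized horseshoe the
#' default global scale is \eqn{\tau_0 = \pi/\sqrt{3NT}}, which follows from
#' the general rule \eqn{\tau_0 = P_0/(P - P_0)\cdot\sigma_\eta/\sqrt{NT}}
#' with a prior guess of 50\% non-zero coefficients and
#' \eqn{\sigma_\eta = \pi/\sqrt 3} (the logistic residual scale); `tau0`
#' accepts a numeric override or the strings `"pi/sqrt(3NT)"`,
#' `"pi/sqrt(NT)"`, `"2/sqrt(NT)"`.
#'
#' @param family prior family.
#' @param sigma_eta scale hyperparameter; numeric, or `"sigma_eps0"` to link
#'   to the model's random-intercept SD (Lasso families only).
#' @param lambda_fixed ridge penalty \eqn{\lambda}.
#' @param a_lambda half-Cauchy scale for the Lasso penalty parameters.
#' @param beta_a,beta_b Beta hyperparameters for the inclusion probabilities.
#' @param nu0 degrees of freedom of the half-Student prior on \eqn{\tau}.
#' @param tau0 global scale \eqn{\tau_0} (see Details).
#' @param nu_c,s_c2 slab hyperparameters of the inverse-Gamma prior on
#'   \eqn{c^2}.
#' @param P0 prior guess of the number of non-zero coefficients (defaults to
#'   `P/2` at fit time).
#' @param name optional preset label.
#' @return An object of class `"msar_prior"`.
#' @seealso [prior_preset()] for the named sensitivity presets.
#' @export
msar_prior <- function(family = c("ridge", "blasso", "abss_lasso", "reg_hs"),
                       sigma_eta = NULL, lambda_fixed = 1, a_lambda = 2.5,
                       beta_a = 0.5, beta_b = 0.5,
                       nu0 = 1, tau0 = "pi/sqrt(3NT)", nu_c = 1, s_c2 = 1,
                       P0 = NULL, name = NULL) {
  family <- match.arg(family)
  if (is.null(sigma_eta)) {
    sigma_eta <- switch(family,
                        ridge = 1,
                        blasso = "sigma_eps0",
                        abss_lasso = "sigma_eps0",
                        reg_hs = pi / sqrt(3))
  }
  if (is.numeric(sigma_eta) && sigma_eta <= 0) {
    stop("msar_prior: sigma_eta must be positive", call. = FALSE)
  }
  for (v in c("lambda_fixed", "a_lambda", "beta_a", "beta_b", "nu0", "nu_c", "s_c2")) {
    if (get(v) <= 0) stop("msar_prior: ", v, " must be positive", call. = FALSE)
  }
  if (!is.null(P0) && (P0 <= 0)) stop("msar_prior: P0 must be positive", call. = FALSE)
  structure(list(family = family, sigma_eta = sigma_eta,
                 lambda_fixed = lambda_fixed, a_lambda = a_lambda,
                 beta_a = beta_a, beta_b = beta_b,
                 nu0 = nu0, tau0 = tau0, nu_c = nu_c, s_c2 = s_c2,
                 P0 = P0,
                 name = if (is.null(name)) family else name),
            class = "msar_prior")
}

#' Named prior presets for the sensitivity analysis
#'
#' Returns the prior specification registered under one of the preset names:
#' `"Ridge-0"` (standard normal), `"Ridge-1"` (\eqn{N(0, 2^2)}), `"B-Lasso"`
#' (Laplace with unit scale and \eqn{\lambda \sim C^+(0, 2.5)}),
#' `"ABSS-Lasso-0"`/`"-1"`/`"-2"` (spike-and-slab Lasso with scale linked to
#' \eqn{\sigma_{\epsilon_0}}, fixed 1, fixed 2), and `"reg-HS-0"`/`"-1"`/
#' `"-2"` (regularized horseshoe with Cauchy slab; lighter
#' \eqn{I\Gamma(2, 8)} slab; lighter slab plus \eqn{t^+_3} global prior with
#' \eqn{\tau_0 = 2/\sqrt{NT}}).
#'
#' @param name preset name (case-insensitive; `"_"` and `"."` accepted for
#'   `"-"`).
#' @return An `"msar_prior"` object.
#' @export
prior_preset <- function(name) {
  key <- toupper(gsub("[._ ]", "-", name))
  spec <- switch(key,
    "RIDGE-0" = msar_prior("ridge", sigma_eta = 1, lambda_fixed = 1),
    "RIDGE-1" = msar_prior("ridge", sigma_eta = 2, lambda_fixed = 1),
    "B-LASSO" = msar_prior("blasso", sigma_eta = 1),
    "ABSS-LASSO-0" = msar_prior("abss_lasso", sigma_eta = "sigma_eps0"),
    "ABSS-LASSO-1" = msar_prior("abss_lasso", sigma_eta = 1),
    "ABSS-LASSO-2" = msar_prior("abss_lasso", sigma_eta = 2),
    "REG-HS-0" = msar_prior("reg_hs", nu0 = 1, tau0 = "pi/sqrt(3NT)",
                            nu_c = 1, s_c2 = 1),
    "REG-HS-1" = msar_prior("reg_hs", nu0 = 1, tau0 = "pi/sqrt(3NT)",
                            nu_c = 4, s_c2 = 4),
    "REG-HS-2" = msar_prior("reg_hs", nu0 = 3, tau0 = "2/sqrt(NT)",
                            nu_c = 4, s_c2 = 4),
    stop("prior_preset: unknown preset '", name, "'", call. = FALSE))
  spec$name <- gsub("LASSO", "Lasso", gsub("REG-HS", "reg-HS", key))
  spec$name <- sub("^RIDGE", "Ridge", spec$name)
  spec
}

#' List the available prior presets
#' @return Character vector of preset names.
#' @export
list_prior_presets <- function() {
  c("Ridge-0", "Ridge-1", "B-Lasso", "ABSS-Lasso-0", "ABSS-Lasso-1",
    "ABSS-Lasso-2", "reg-HS-0", "reg-HS-1", "reg-HS-2")
}

#' @export
print.msar_prior <- function(x, ...) {
  cat(sprintf("msar_prior: %s (family %s)\n", x$name, x$family))
  cat("  sigma_eta =", if (is.character(x$sigma_eta)) x$sigma_eta
      else format(x$sigma_eta), "\n")
  if (x$family == "ridge") cat("  lambda =", x$lambda_fixed, "\n")
  if (x$family %in% c("blasso", "abss_lasso")) cat("  a_lambda =", x$a_lambda, "\n")
  if (x$family == "abss_lasso") {
    cat(sprintf("  nu_p ~ Beta(%g, %g)\n", x$beta_a, x$beta_b))
  }
  if (x$family == "reg_hs") {
    cat(sprintf("  nu0 = %g, tau0 = %s, c^2 ~ IG(%g/2, %g*%g/2)\n",
                x$nu0, if (is.character(x$tau0)) x$tau0 else format(x$tau0),
                x$nu_c, x$nu_c, x$s_c2))
  }
  invisible(x)
}

## resolve the global-scale rule of the regularized horseshoe
resolve_tau0 <- function(spec, N, T) {
  t0 <- spec$tau0
  if (is.numeric(t0)) return(t0)
  switch(t0,
         "pi/sqrt(3NT)" = pi / sqrt(3 * N * T),
         "pi/sqrt(NT)"  = pi / sqrt(N * T),
         "2/sqrt(NT)"   = 2 / sqrt(N * T),
         stop("resolve_tau0: unknown tau0 rule '", t0, "'", call. = FALSE))
}

resolve_sigma_eta <- function(spec, sigma_eps0 = NULL) {
  if (is.numeric(spec$sigma_eta)) return(spec$sigma_eta)
  if (identical(spec$sigma_eta, "sigma_eps0")) {
    if (is.null(sigma_eps0)) {
      stop("resolve_sigma_eta: sigma_eps0 required for the linked scale",
           call. = FALSE)
    }
    return(sigma_eps0)
  }
  stop("resolve_sigma_eta: invalid sigma_eta", call. = FALSE)
}

## -- log-prior operations ----------------------------------------------------

#' Ridge log-prior for the slope vector
#'
#' Sum of \eqn{N(0, \sigma_\eta^2/\lambda)} log-densities.
#'
#' @param beta slope vector.
#' @param spec an `"msar_prior"` with `family = "ridge"`.
#' @return Scalar log-density.
#' @export
ridge_logprior <- function(beta, spec = msar_prior("ridge")) {
  stopifnot(spec$family == "ridge")
  sdv <- spec$sigma_eta / sqrt(spec$lambda_fixed)
  sum(dnorm(beta, 0, sdv, log = TRUE))
}

#' Bayesian-Lasso log-prior
#'
#' Laplace log-densities for the slopes with scale \eqn{\sigma_\eta/\lambda},
#' plus the half-Cauchy log-density of the penalty \eqn{\lambda}.
#'
#' @param beta slope vector.
#' @param lambda penalty parameter (> 0).
#' @param sigma_eta numeric scale (resolve the linked scale before calling).
#' @param spec an `"msar_prior"` with `family = "blasso"`.
#' @return Scalar log-density.
#' @export
blasso_logprior <- function(beta, lambda, sigma_eta = 1,
                            spec = msar_prior("blasso", sigma_eta = 1)) {
  if (lambda <= 0) stop("blasso_logprior: lambda must be positive", call. = FALSE)
  sum(dlaplace_log(beta, sigma_eta / lambda)) +
    dhalfcauchy_log(lambda, spec$a_lambda)
}

#' Adaptive spike-and-slab Lasso log-prior
#'
#' Joint log-density of the raw coefficients \eqn{\bar\beta_p} (Laplace with
#' per-coefficient scale \eqn{\sigma_\eta/\lambda_p}), the inclusion
#' probabilities \eqn{\nu_p} (Beta), and the penalties \eqn{\lambda_p}
#' (half-Cauchy), together with the deterministic product
#' \eqn{\beta_p = \bar\beta_p \nu_p}.
#'
#' @param beta_bar raw coefficient vector.
#' @param nu inclusion probabilities in (0, 1).
#' @param lambda_p per-coefficient penalties (> 0).
#' @param sigma_eta numeric scale.
#' @param spec an `"msar_prior"` with `family = "abss_lasso"`.
#' @return List with `logp` (scalar) and `beta` (the elementwise product).
#' @export
abss_logprior <- function(beta_bar, nu, lambda_p, sigma_eta = 1,
                          spec = msar_prior("abss_lasso", sigma_eta = 1)) {
  stopifnot(all(nu > 0 & nu < 1), all(lambda_p > 0))
  logp <- sum(dlaplace_log(beta_bar, sigma_eta / lambda_p)) +
    sum(dbeta(nu, spec$beta_a, spec$beta_b, log = TRUE)) +
    sum(dhalfcauchy_log(lambda_p, spec$a_lambda))
  list(logp = logp, beta = beta_bar * nu)
}

#' Regularized-horseshoe log-prior
#'
#' Normal log-density of the slopes with SD \eqn{\tilde\lambda_p \tau}, where
#' \eqn{\tilde\lambda_p = \sqrt{c^2\lambda_p^2 / (c^2 + \tau^2\lambda_p^2)}},
#' plus the hyperprior log-densities of the local scales (half-Cauchy),
#' the global scale (half-Student with scale \eqn{\tau_0}) and the slab
#' variance (inverse-Gamma).
#'
#' @param beta slope vector.
#' @param lambda_p local scales (> 0).
#' @param tau global scale (> 0).
#' @param c2 slab variance (> 0).
#' @param spec an `"msar_prior"` with `family = "reg_hs"`.
#' @param N,T sample sizes used to resolve \eqn{\tau_0}.
#' @return Scalar log-density.
#' @export
reg_hs_logprior <- function(beta, lambda_p, tau, c2,
                            spec = msar_prior("reg_hs"), N, T) {
  stopifnot(all(lambda_p > 0), tau > 0, c2 > 0)
  tau0 <- resolve_tau0(spec, N, T)
  lt <- hs_lambda_tilde(lambda_p, tau, c2)
  sum(dnorm(beta, 0, lt * tau, log = TRUE)) +
    sum(dhalfcauchy_log(lambda_p, 1)) +
    dhalfstudent_log(tau, spec$nu0, tau0) +
    dinvgamma_log(c2, spec$nu_c / 2, spec$nu_c * spec$s_c2 / 2)
}

#' Effective local scale of the regularized horseshoe
#'
#' \eqn{\tilde\lambda_p = \sqrt{c^2 \lambda_p^2 / (c^2 + \tau^2 \lambda_p^2)}}.
#' For \eqn{\tau^2\lambda_p^2 \ll c^2} this reduces to \eqn{\lambda_p} (the
#' original horseshoe regime); for \eqn{\lambda_p \to \infty} the product
#' \eqn{\tilde\lambda_p \tau} is bounded by \eqn{c} (the slab regime).
#'
#' @param lambda_p local scales.
#' @param tau global scale.
#' @param c2 slab variance.
#' @return Vector of effective scales.
#' @export
hs_lambda_tilde <- function(lambda_p, tau, c2) {
  sqrt(c2 * lambda_p^2 / (c2 + tau^2 * lambda_p^2))
}

#' Weakly informative baseline log-priors for the non-shrunken parameters
#'
#' Sums the baseline priors: half-Cauchy(0, 2.5) for every standard deviation
#' (residual SDs and the random-intercept SD), half-normal(0, 10) for the
#' fixed intercept and the state-2 latent intercept, standard normal for the
#' state-2 autoregressive coefficients and the covariate effect, and (for
#' `K > 1`) an LKJ(4) term for the residual correlation matrix, up to its
#' normalizing constant.
#'
#' @param w a [within_params()] object.
#' @param b a [between_params()] object.
#' @param lambda_free optional vector of free factor loadings
#'   (half-normal(0, 1)).
#' @return Scalar log-density. The state-1 constraints contribute nothing.
#' @export
baseline_logpriors <- function(w, b, lambda_free = NULL) {
  if (any(w$tau_eps <= 0) || b$sigma_eps0 < 0) {
    stop("baseline_logpriors: scale parameters outside their domain", call. = FALSE)
  }
  lp <- sum(dhalfcauchy_log(w$tau_eps, 2.5)) +
    dhalfcauchy_log(b$sigma_eps0, 2.5) +
    dhalfnormal_log(b$beta0, 10) +
    sum(dhalfnormal_log(w$A2, 10)) +
    sum(dnorm(w$B2, 0, 1, log = TRUE)) +
    dnorm(w$gamma, 0, 1, log = TRUE)
  if (w$K > 1) {
    R <- w$Omega_eps %*% t(w$Omega_eps)
    lp <- lp + dlkj_log_unnorm(R, 4.0)
  }
  if (!is.null(lambda_free)) {
    lp <- lp + sum(dhalfnormal_log(lambda_free, 1))
  }
  lp
}

#' Marginal prior density curves at fixed hyperparameter values
#'
#' Evaluates, on a grid, the marginal density of a slope under each family
#' with its hyperparameters held fixed (not hierarchical): normal for the
#' ridge, Laplace for the B-Lasso, a scaled Laplace for the spike-and-slab
#' Lasso at a fixed inclusion probability, and for the regularized horseshoe
#' the numeric marginal over the half-Cauchy local scale at fixed
#' \eqn{(\tau, c^2)}.
#'
#' @param family one of `"ridge"`, `"blasso"`, `"abss_lasso"`, `"reg_hs"`.
#' @param grid numeric vector of evaluation points.
#' @param sigma_eta,lambda scale and penalty for the ridge / Lasso curves.
#' @param nu fixed inclusion probability (spike-and-slab curve).
#' @param tau,c2 fixed global scale and slab variance (horseshoe curve).
#' @return Numeric vector of densities on `grid`.
#' @export
prior_density_curve <- function(family, grid, sigma_eta = 2, lambda = 2,
                                nu = 0.5, tau = 2 / sqrt(50), c2 = 4) {
  switch(family,
    ridge = dnorm(grid, 0, sigma_eta / sqrt(lambda)),
    blasso = exp(dlaplace_log(grid, sigma_eta / lambda)),
    abss_lasso = exp(dlaplace_log(grid, nu * sigma_eta / lambda)),
    reg_hs = vapply(grid, function(x) {
      integrate(function(l) {
        lt <- hs_lambda_tilde(l, tau, c2)
        dnorm(x, 0, lt * tau) * 2 / (pi * (1 + l^2))
      }, 0, Inf, rel.tol = 1e-9, stop.on.error = FALSE)$value
    }, numeric(1)),
    stop("prior_density_curve: unknown family '", family, "'", call. = FALSE))
}
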