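test_that("ridge log-prior matches the normal closed form", {
  P <- 7
  expect_equal(ridge_logprior(rep(0, P), prior_preset("Ridge-0")),
               P * (-0.918938533204673), tolerance = 1e-12)
  ## Ridge-1 doubles the SD: each term drops by log 2 at the origin
  expect_equal(ridge_logprior(rep(0, P), prior_preset("Ridge-1")),
               P * (-0.918938533204673 - log(2)), tolerance = 1e-12)
  beta <- rnorm(P)
  expect_equal(ridge_logprior(beta), ridge_logprior(-beta))
})

test_that("B-Lasso log-prior: Laplace and half-Cauchy closed forms", {
  ## Laplace(0, b) at 0 is -log(2b)
  expect_equal(blasso_logprior(0, lambda = 1, sigma_eta = 3) -
                 dhalfcauchy_log(1, 2.5), -log(2 * 3), tolerance = 1e-12)
  ## half-Cauchy density at 0 with scale 2.5 is 2/(pi * 2.5)
  expect_equal(dhalfcauchy_log(1e-300, 2.5), log(2 / (pi * 2.5)),
               tolerance = 1e-9)
  expect_error(blasso_logprior(0, lambda = -1), "positive")
})

test_that("normal-exponential scale mixture reproduces the Laplace density", {
  ## beta | tau2 ~ N(0, sigma^2 tau2), tau2 ~ Exp(lambda^2 / 2)
  ## integrates to Laplace(0, sigma / lambda)
  sigma <- 1.3; lambda <- 0.8
  for (beta in seq(-5, 5, by = 0.5)) {
    mix <- integrate(function(v) {
      dnorm(beta, 0, sigma * sqrt(v)) * (lambda^2 / 2) * exp(-lambda^2 * v / 2)
    }, 0, Inf, rel.tol = 1e-12)$value
    expect_equal(mix, exp(dlaplace_log(beta, sigma / lambda)),
                 tolerance = 1e-6)
  }
})

test_that("spike-and-slab Lasso prior: product construction and Beta closed form", {
  spec <- prior_preset("ABSS-Lasso-1")
  out <- abss_logprior(beta_bar = c(2, -1), nu = c(0.3, 0.7),
                       lambda_p = c(1, 2), sigma_eta = 1, spec = spec)
  expect_equal(out$beta, c(2 * 0.3, -1 * 0.7))
  ## Beta(1/2, 1/2) density at 1/2 is 2/pi
  expect_equal(dbeta(0.5, 0.5, 0.5, log = TRUE), -log(pi / 2),
               tolerance = 1e-12)
  ## nu -> 0 forces beta -> 0 whatever beta_bar
  out0 <- abss_logprior(1e6, 1e-12, 1, 1, spec)
  expect_lt(abs(out0$beta), 1e-5)
})

test_that("regularized horseshoe: scale formula limits and tau0 arithmetic", {
  ## tau^2 lambda^2 << c^2: original horseshoe regime
  expect_equal(hs_lambda_tilde(2, 1e-8, 4), 2, tolerance = 1e-10)
  ## lambda -> Inf: slab regime, SD bounded by c
  tau <- 0.3
  expect_equal(hs_lambda_tilde(1e12, tau, 4) * tau, 2, tolerance = 1e-6)
  ## default global scale at N = 100, T = 50
  expect_equal(resolve_tau0(prior_preset("reg-HS-0"), 100, 50),
               0.02565, tolerance = 1e-4)
  expect_equal(resolve_tau0(prior_preset("reg-HS-0"), 100, 50),
               pi / sqrt(3 * 100 * 50), tolerance = 1e-12)
  ## the reg-HS-2 variant switches the rule
  expect_equal(resolve_tau0(prior_preset("reg-HS-2"), 100, 50),
               2 / sqrt(100 * 50), tolerance = 1e-12)
  lp <- reg_hs_logprior(c(0.1, -0.2), c(1, 2), 0.05, 1.2,
                        prior_preset("reg-HS-0"), N = 50, T = 20)
  expect_true(is.finite(lp))
})

test_that("presets carry the catalog hyperparameters", {
  expect_equal(prior_preset("Ridge-0")$sigma_eta, 1)
  expect_equal(prior_preset("Ridge-1")$sigma_eta, 2)
  expect_equal(prior_preset("B-Lasso")$a_lambda, 2.5)
  expect_equal(prior_preset("B-Lasso")$sigma_eta, 1)
  expect_identical(prior_preset("ABSS-Lasso-0")$sigma_eta, "sigma_eps0")
  expect_equal(prior_preset("ABSS-Lasso-2")$sigma_eta, 2)
  expect_equal(prior_preset("ABSS-Lasso-0")$beta_a, 0.5)
  ## reg-HS-1 slab IG(2, 8) corresponds to nu_c = 4, s_c^2 = 4
  p1 <- prior_preset("reg-HS-1")
  expect_equal(c(p1$nu_c / 2, p1$nu_c * p1$s_c2 / 2), c(2, 8))
  expect_equal(prior_preset("reg-HS-2")$nu0, 3)
  expect_error(prior_preset("no-such"), "unknown")
  expect_setequal(list_prior_presets(),
                  c("Ridge-0", "Ridge-1", "B-Lasso", "ABSS-Lasso-0",
                    "ABSS-Lasso-1", "ABSS-Lasso-2", "reg-HS-0", "reg-HS-1",
                    "reg-HS-2"))
})

test_that("baseline priors follow the weakly informative catalog", {
  w <- within_params(A2 = 0, B2 = 0, gamma = 0, sigma_eps = 1)
  w$A2 <- 0  # evaluate the half-normal at its maximum
  b <- between_params(beta0 = 0, beta_x = numeric(0), sigma_eps0 = 1)
  lp <- baseline_logpriors(w, b)
  ## components: two half-Cauchy(.,2.5) at 1, two half-normal(0,10) at 0,
  ## N(0,1) at 0 twice (B2 and gamma)
  ref <- 2 * dhalfcauchy_log(1, 2.5) +
    2 * (log(2) - 0.5 * log(2 * pi * 100)) +
    2 * dnorm(0, log = TRUE)
  expect_equal(lp, ref, tolerance = 1e-12)
  ## half-normal(0,10) closed form at 0
  expect_equal(dhalfnormal_log(0, 10), log(2) - 0.5 * log(2 * pi * 100),
               tolerance = 1e-12)
})

test_that("LKJ(4) term peaks at the identity correlation", {
  Om_id <- diag(2)
  Om_c <- t(chol(matrix(c(1, 0.5, 0.5, 1), 2)))
  w_id <- within_params(A2 = c(1, 1), B2 = diag(2) * 0.1, gamma = 0,
                        tau_eps = c(1, 1), Omega_eps = Om_id)
  w_c <- within_params(A2 = c(1, 1), B2 = diag(2) * 0.1, gamma = 0,
                       tau_eps = c(1, 1), Omega_eps = Om_c)
  b <- between_params(beta0 = 1, beta_x = numeric(0), sigma_eps0 = 1)
  expect_gt(baseline_logpriors(w_id, b), baseline_logpriors(w_c, b))
})

test_that("fixed-hyperparameter marginal priors integrate to 1", {
  grid_int <- function(family, ...) {
    integrate(function(x) prior_density_curve(family, x, ...),
              -Inf, Inf, rel.tol = 1e-8)$value
  }
  expect_equal(grid_int("ridge"), 1, tolerance = 1e-4)
  expect_equal(grid_int("blasso"), 1, tolerance = 1e-4)
  ## spike-and-slab at fixed inclusion: mass conserved including near zero
  expect_equal(grid_int("abss_lasso"), 1, tolerance = 1e-4)
  hs <- integrate(function(x) prior_density_curve("reg_hs", x),
                  -20, 20, rel.tol = 1e-6)$value
  expect_equal(hs, 1, tolerance = 1e-4)
})

test_that("density curves match closed forms and concentrate as expected", {
  ## ridge with sigma_eta = 2, lambda = 1 is N(0, 4)
  expect_equal(prior_density_curve("ridge", 0, sigma_eta = 2, lambda = 1),
               1 / (2 * sqrt(2 * pi)), tolerance = 1e-12)
  ## Laplace curve at 0 with scale 1 is 1/2
  expect_equal(prior_density_curve("blasso", 0, sigma_eta = 2, lambda = 2),
               0.5, tolerance = 1e-12)
  g <- seq(-3, 3, by = 0.25)
  for (fam in c("ridge", "blasso", "abss_lasso", "reg_hs")) {
    expect_equal(prior_density_curve(fam, g), prior_density_curve(fam, -g),
                 tolerance = 1e-8)
  }
  ## at the origin the Lasso-type densities exceed the ridge density
  ridge0 <- prior_density_curve("ridge", 0)
  expect_gt(prior_density_curve("blasso", 0), ridge0)
  expect_gt(prior_density_curve("abss_lasso", 0), ridge0)
  expect_error(prior_density_curve("cauchy", 0), "unknown family")
})

test_that("log-prior operations are finite and differentiable inside the domain", {
  h <- 1e-6
  f <- function(x) blasso_logprior(c(0.5, -1), lambda = x, sigma_eta = 1)
  g_fd <- (f(1 + h) - f(1 - h)) / (2 * h)
  expect_true(is.finite(g_fd))
  f2 <- function(x) reg_hs_logprior(c(0.3, x), c(1, 1), 0.1, 2,
                                    prior_preset("reg-HS-0"), 50, 20)
  expect_true(is.finite((f2(0.2 + h) - f2(0.2 - h)) / (2 * h)))
})
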