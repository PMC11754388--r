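## shared fixture builders and numeric helpers

## central finite differences of a scalar function
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

## random small parameter set for filter tests
random_params <- function() {
  list(
    w = within_params(A2 = runif(1, 0.5, 3), B2 = runif(1, -0.9, 0.9),
                      gamma = rnorm(1, 0, 0.5),
                      sigma_eps = runif(1, 0.2, 1)),
    b = between_params(beta0 = rnorm(1, 1, 1), beta_x = rnorm(2, 0, 0.5),
                       beta_z = rnorm(1, 0, 0.3), beta_xz = rnorm(2, 0, 0.3),
                       sigma_eps0 = 1, p21 = runif(1, 0.01, 0.3))
  )
}

random_panel <- function(N = 3, Tn = 10, Q = 2, with_z = TRUE) {
  panel_dataset(matrix(rnorm(N * Tn, 1, 1.5), N, Tn),
                matrix(rnorm(N * Q), N, Q),
                eta_z = if (with_z) matrix(rnorm(N * Tn), N, Tn))
}

## tiny dataset + posterior for gradient tests
tiny_posterior <- function(family, include_mu1 = FALSE, seed = 3,
                           N = 8, Tn = 12, P = 4, ...) {
  d <- if (include_mu1) generate_sim2(sim2_design(N = N, T = Tn, seed = seed))
       else generate_sim1(sim1_design(N = N, T = Tn, P = P, seed = seed))
  build_log_posterior(d, msar_prior(family, ...), include_mu1 = include_mu1)
}

expect_rel_equal <- function(x, y, tol = 1e-6) {
  expect_lt(max(abs(x - y) / pmax(1, abs(y))), tol)
}
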