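test_that("transition-predictor components reproduce hand arithmetic", {
  ## mu0
  expect_equal(compute_mu0(3, c(0, 0), matrix(rnorm(6), 3, 2), rep(0, 3)),
               rep(3, 3))
  expect_equal(compute_mu0(0, c(1, 0), matrix(c(0.5, 9), 1, 2), 0), 0.5)
  expect_equal(compute_mu0(3, c(0.5, -0.5), matrix(c(1, 1), 1, 2), 0.2), 3.2)
  ## mu1
  ez <- matrix(2, 1, 1)
  expect_equal(compute_mu1(0.5, 0, ez, matrix(1, 1, 1)), matrix(1.0, 1, 1))
  expect_equal(compute_mu1(0.5, 0.5, matrix(1, 1, 1), matrix(1, 1, 1)),
               matrix(1.0, 1, 1))
  expect_true(all(compute_mu1(2, c(1, -1), matrix(0, 3, 4),
                              matrix(rnorm(6), 3, 2)) == 0))
  ## mu2 (K = 1): at t = 2 with lag value 2
  ey <- array(c(2, 7), c(1, 2, 1))
  expect_equal(compute_mu2(0.3, 0.2, ey, matrix(1, 1, 1))[1, 2], 1.0)
  expect_equal(compute_mu2(0.3, 0.2, ey, matrix(1, 1, 1))[1, 1], 0)  # no lag at t=1
  ## ordering contract: first Kronecker slot pairs eta_x1 with eta_y
  a <- 0.7; b <- -0.3; cc <- 2; by <- 0.4
  ey <- array(c(cc, 1), c(1, 2, 1))
  out <- compute_mu2(by, c(1, 0), ey, matrix(c(a, b), 1, 2))[1, 2]
  expect_equal(out, by * cc + a * cc)
})

test_that("mu2 is invariant to jointly permuting covariates and slope blocks", {
  set.seed(1)
  N <- 4; Tn <- 6; K <- 2; Q <- 3
  ey <- array(rnorm(N * Tn * K), c(N, Tn, K))
  X <- matrix(rnorm(N * Q), N, Q)
  beta_y <- rnorm(K)
  beta_xy <- rnorm(K * Q)
  perm <- c(3, 1, 2)
  ## block q of beta_xy pairs with covariate q
  Bm <- matrix(beta_xy, K, Q)
  out1 <- compute_mu2(beta_y, beta_xy, ey, X)
  out2 <- compute_mu2(beta_y, as.numeric(Bm[, perm]), ey, X[, perm])
  expect_equal(out1, out2)
})

test_that("dimension mismatches raise structured errors", {
  expect_error(compute_mu0(0, c(1, 2, 3), matrix(0, 2, 2), c(0, 0)),
               "covariates")
  expect_error(compute_mu0(0, c(1, 2), matrix(0, 2, 2), c(0, 0, 0)),
               "individuals")
  expect_error(compute_mu1(1, 0.5, NULL, matrix(0, 2, 2)), "absent")
  expect_error(compute_mu2(0.3, c(0.2, 0.1, 0.4), array(0, c(2, 3, 1)),
                           matrix(0, 2, 2)), "K\\*Q")
})

test_that("stay probability is a stable logistic", {
  expect_equal(stay_probability(0), 0.5)
  expect_equal(stay_probability(3), 0.952574126822433, tolerance = 1e-12)
  expect_equal(stay_probability(-1e6), 0)
  expect_equal(stay_probability(1e6), 1)
  x <- seq(-30, 30, length.out = 101)
  expect_equal(stay_probability(x) + stay_probability(-x), rep(1, 101))
})

test_that("transition matrix is row-stochastic with the stated layout", {
  P <- transition_matrix(0.5, 0.05)
  expect_equal(unname(P), matrix(c(0.5, 0.5, 0.05, 0.95), 2, byrow = TRUE))
  expect_equal(unname(transition_matrix(1, 0.3)[1, ]), c(1, 0))
  for (p11 in runif(10)) {
    expect_equal(unname(rowSums(transition_matrix(p11, runif(1)))), c(1, 1))
  }
  expect_error(transition_matrix(1.2, 0.05), "\\[0, 1\\]")
})

test_that("state-conditional log-density matches the normal closed form", {
  w1 <- within_params(A2 = 3, B2 = 0.8, gamma = 0, sigma_eps = 1)
  expect_equal(state_conditional_logdensity(0, 0, 0, 1, w1),
               -0.918938533204673, tolerance = 1e-12)
  w2 <- within_params(A2 = 3, B2 = 0.8, gamma = 0.5, sigma_eps = 0.25)
  ## observation at the conditional mean: density peak
  expect_equal(state_conditional_logdensity(3, 0, 0, 2, w2),
               -log(0.25 * sqrt(2 * pi)), tolerance = 1e-12)
  ## symmetry about the mean
  m <- 3 + 0.8 * 1 + 0.5 * 2
  expect_equal(state_conditional_logdensity(m + 0.7, 1, 2, 2, w2),
               state_conditional_logdensity(m - 0.7, 1, 2, 2, w2))
  expect_error(state_conditional_logdensity(0, 0, 0, 3, w1), "1 or 2")
})

test_that("K = 1 state-conditional density integrates to 1 by quadrature", {
  w <- within_params(A2 = 2, B2 = 0.5, gamma = 0.3, sigma_eps = 0.4)
  for (s in 1:2) {
    v <- integrate(function(x) {
      vapply(x, function(xx)
        exp(state_conditional_logdensity(xx, 1.2, -0.5, s, w)), numeric(1))
    }, -Inf, Inf)$value
    expect_equal(v, 1, tolerance = 1e-6)
  }
})

test_that("K = 2 density uses the Cholesky-built covariance", {
  Om <- t(chol(matrix(c(1, 0.4, 0.4, 1), 2)))
  w <- within_params(A2 = c(1, 2), B2 = diag(c(0.5, 0.3)), gamma = 0.2,
                     tau_eps = c(0.5, 1.2), Omega_eps = Om)
  Sigma <- diag(c(0.5, 1.2)) %*% Om %*% t(Om) %*% diag(c(0.5, 1.2))
  yt <- c(0.3, -0.8); yp <- c(1, 0.5); zt <- 0.7
  m <- c(1, 2) + diag(c(0.5, 0.3)) %*% yp + c(0.2, 0) * zt
  r <- yt - drop(m)
  ref <- -log(2 * pi) - 0.5 * determinant(Sigma)$modulus[1] -
    0.5 * drop(r %*% solve(Sigma, r))
  expect_equal(state_conditional_logdensity(yt, yp, zt, 2, w), unname(ref),
               tolerance = 1e-10)
})

test_that("measurement layer: identity mapping contributes 0, normal otherwise", {
  m0 <- measurement_params(Lambda_y = matrix(1), Sigma_y = 0)
  lat <- list(eta_y = array(rnorm(6), c(2, 3, 1)))
  Y <- array(lat$eta_y, c(2, 3, 1))
  expect_equal(measurement_loglik(Y = Y, latents = lat, m = m0), 0)
  ## single item, loading 1, sd 1, y == eta: standard normal log-pdf at 0
  m1 <- measurement_params(Lambda_y = matrix(1), Sigma_y = 1)
  lat1 <- list(eta_y = array(0.7, c(1, 1, 1)))
  Y1 <- array(0.7, c(1, 1, 1))
  expect_equal(measurement_loglik(Y = Y1, latents = lat1, m = m1),
               -0.918938533204673, tolerance = 1e-12)
  ## doubling sigma lowers the attainable maximum by log 2
  m2 <- measurement_params(Lambda_y = matrix(1), Sigma_y = 4)
  expect_equal(measurement_loglik(Y = Y1, latents = lat1, m = m1) -
                 measurement_loglik(Y = Y1, latents = lat1, m = m2),
               log(2), tolerance = 1e-12)
  expect_error(measurement_loglik(Y = array(0, c(1, 1, 2)), latents = lat1,
                                  m = m1), "shape")
})

test_that("panel dataset validates its invariants", {
  y <- matrix(rnorm(6), 2, 3)
  x <- matrix(rnorm(4), 2, 2)
  expect_s3_class(panel_dataset(y, x), "msar_panel")
  expect_error(panel_dataset(y, x[1, , drop = FALSE]), "individuals")
  expect_error(panel_dataset(y, x, states = matrix(2L, 2, 3)), "state 1")
  ybad <- y; ybad[1] <- NA
  expect_error(panel_dataset(ybad, x), "missing")
})
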