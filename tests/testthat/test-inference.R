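test_that("analytic posterior gradient matches finite differences everywhere", {
  set.seed(31)
  for (fam in c("ridge", "blasso", "abss_lasso", "reg_hs")) {
    for (mu1 in c(FALSE, TRUE)) {
      post <- tiny_posterior(fam, include_mu1 = mu1)
      for (r in 1:2) {
        th <- post$init()
        res <- post$lp_grad(th)
        gfd <- fd_grad(function(x) post$lp_grad(x)$value, th)
        expect_rel_equal(res$grad, gfd, tol = 1e-5)
      }
    }
  }
})

test_that("stacking two copies of the data doubles the likelihood term", {
  d <- generate_sim1(sim1_design(N = 6, T = 10, P = 3, seed = 9))
  d2 <- panel_dataset(
    rbind(d$eta_y[, , 1], d$eta_y[, , 1]),
    rbind(d$eta_x, d$eta_x),
    eta_z = rbind(d$eta_z, d$eta_z))
  prior <- msar_prior("ridge")
  p1 <- build_log_posterior(d, prior)
  p1_0 <- build_log_posterior(d, prior, likelihood = FALSE)
  p2 <- build_log_posterior(d2, prior)
  p2_0 <- build_log_posterior(d2, prior, likelihood = FALSE)
  set.seed(5)
  th1 <- p1$init()
  ## duplicate the eps0 block to build the stacked parameter vector
  N <- d$N
  th2 <- c(th1[1:6], th1[6 + 1:N], th1[6 + 1:N], th1[-(1:(6 + N))])
  ll1 <- p1$lp_grad(th1)$value - p1_0$lp_grad(th1)$value
  ll2 <- p2$lp_grad(th2)$value - p2_0$lp_grad(th2)$value
  expect_equal(ll2, 2 * ll1, tolerance = 1e-9)
})

test_that("prior-only posterior: gradient vanishes at the optimum", {
  d <- generate_sim1(sim1_design(N = 4, T = 6, P = 3, seed = 2))
  post <- build_log_posterior(d, msar_prior("ridge"), likelihood = FALSE)
  set.seed(8)
  opt <- optim(post$init(), fn = function(th) -post$lp_grad(th)$value,
               gr = function(th) -post$lp_grad(th)$grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(max(abs(post$lp_grad(opt$par)$grad)), 1e-4)
})

test_that("posterior builder validates its inputs", {
  d <- generate_sim1(sim1_design(N = 4, T = 6, P = 3, seed = 2))
  d$eta_z <- NULL
  expect_error(build_log_posterior(d, msar_prior("ridge"), include_mu1 = TRUE),
               "eta_z")
  expect_error(sampler_config(iter = 100, warmup = 200), "iter")
})

test_that("non-finite parameter points are rejected, not fatal", {
  post <- tiny_posterior("ridge")
  th <- post$init()
  th[5] <- 1e4  # sigma_eps = exp(1e4) overflows
  r <- post$lp_grad(th)
  expect_identical(r$value, -Inf)
  th[5] <- NA
  expect_identical(post$lp_grad(th)$value, -Inf)
})

test_that("NUTS recovers a known Gaussian target deterministically", {
  lpg <- function(th) list(value = -0.5 * sum(th^2 / c(1, 4, 0.25)),
                           grad = -th / c(1, 4, 0.25))
  cfg <- sampler_config(chains = 2, iter = 1200, warmup = 400, seed = 2)
  s1 <- sample_posterior(lpg, cfg, n_par = 3)
  flat <- matrix(s1$draws, ncol = 3)
  expect_lt(max(abs(colMeans(flat))), 0.15)
  expect_equal(apply(flat, 2, sd), c(1, 2, 0.5), tolerance = 0.12)
  ## determinism under the same seed
  s2 <- sample_posterior(lpg, cfg, n_par = 3)
  expect_identical(s1$draws, s2$draws)
})

test_that("with the likelihood off, ridge slope draws match their N(0,1) prior", {
  d <- generate_sim1(sim1_design(N = 4, T = 5, P = 3, seed = 3))
  post <- build_log_posterior(d, prior_preset("Ridge-0"), likelihood = FALSE)
  s <- sample_posterior(post, sampler_config(chains = 2, iter = 1600,
                                             warmup = 400, seed = 9))
  ## beta block sits right after the 6 + N core parameters
  bidx <- 6 + 4 + 1
  draws <- as.vector(s$draws[, , bidx])
  probs <- seq(0.1, 0.9, by = 0.1)
  expect_lt(max(abs(quantile(draws, probs) - qnorm(probs))), 0.12)
})

test_that("the brute-force tuning preset tightens the sampler settings", {
  cfg <- sampler_config(brute_force = TRUE)
  expect_equal(cfg$target_accept, 0.999)
  expect_equal(cfg$step_size, 0.001)
})

test_that("posterior contracts as the panel grows", {
  ## same generating law, 12x more observations: posterior SDs of the
  ## within-level parameters shrink and the truths stay covered
  small <- generate_sim1(sim1_design(N = 15, T = 8, P = 3, seed = 6))
  big <- generate_sim1(sim1_design(N = 45, T = 32, P = 3, seed = 6))
  f_small <- msar(small, prior = "Ridge-0", chains = 2, iter = 500,
                  warmup = 250, seed = 4)
  f_big <- msar(big, prior = "Ridge-0", chains = 2, iter = 500,
                warmup = 250, seed = 4)
  for (p in c("A2", "B2", "sigma_eps")) {
    expect_lt(f_big$summary[p, "sd"], f_small$summary[p, "sd"])
  }
  truth <- c(A2 = 3, B2 = 0.8, sigma_eps = 0.25)
  for (p in names(truth)) {
    expect_gt(truth[[p]], f_big$summary[p, "lower"])
    expect_lt(truth[[p]], f_big$summary[p, "upper"])
  }
})

test_that("fit object methods are coherent", {
  d <- generate_sim1(sim1_design(N = 10, T = 8, P = 3, seed = 12))
  fit <- msar(d, prior = "Ridge-0", chains = 2, iter = 300, warmup = 150,
              seed = 2)
  expect_s3_class(fit, "msar_fit")
  expect_length(coef(fit), 3)
  s <- summary(fit)
  expect_true(all(c("mean", "sd", "lower", "upper") %in% names(s)))
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  ## HPD intervals exist and agree with equal-tailed ones for symmetric draws
  sh <- summary(fit, interval = "hpd")
  expect_true(all(is.finite(sh$lower) & is.finite(sh$upper)))
  sym <- array(rnorm(20000), c(5000, 4, 1), dimnames = list(NULL, NULL, "x"))
  se <- summarize(sym); shp <- summarize(sym, interval = "hpd")
  expect_equal(shp["x", "lower"], se["x", "lower"], tolerance = 0.05)
  expect_equal(shp["x", "upper"], se["x", "upper"], tolerance = 0.05)
  r <- residuals(fit)
  expect_equal(dim(r), c(10, 8))
  expect_true(all(is.na(r[, 1])))
  expect_true(all(is.finite(r[, -1])))
  xi <- fitted(fit)
  expect_true(all(xi >= 0 & xi <= 1))
  expect_equal(xi[, 1], rep(1, 10))
  mode <- posterior_mode(fit, maxit = 50)
  expect_true(all(is.finite(mode)))
  expect_equal(names(mode), fit$posterior$nat_names)
  sim <- simulate(fit, nsim = 1, seed = 3)
  expect_s3_class(sim[[1]], "msar_sim")
  expect_output(print(fit), "Markov-switching")
})

test_that("posterior summaries behave on degenerate and exact draws", {
  arr <- array(rnorm(4000), c(500, 4, 2),
               dimnames = list(NULL, NULL, c("a", "b")))
  arr[, , 2] <- 1.5  # constant parameter
  s <- summarize(arr)
  expect_equal(s["b", "mean"], 1.5)
  expect_equal(s["b", "lower"], 1.5)
  expect_equal(s["b", "upper"], 1.5)
  ## empirical 95% quantiles of many standard normal draws
  set.seed(1)
  big <- array(rnorm(1e4), c(2500, 4, 1), dimnames = list(NULL, NULL, "x"))
  sb <- summarize(big)
  expect_equal(sb["x", "lower"], -1.96, tolerance = 0.08)
  expect_equal(sb["x", "upper"], 1.96, tolerance = 0.08)
  expect_error(summarize(array(1, c(1, 1, 1), dimnames = list(NULL, NULL, "x"))),
               "too few")
})
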