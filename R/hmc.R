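## Gradient-based sampler: No-U-Turn Hamiltonian Monte Carlo with
## dual-averaging step-size adaptation and a diagonal mass matrix estimated
## during warmup (initial buffer, expanding windows, terminal buffer).

#' Sampler configuration
#'
#' @param chains number of chains.
#' @param iter total iterations per chain (including warmup).
#' @param warmup number of warmup (adaptation) iterations.
#' @param seed integer seed; chain seeds are derived deterministically.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param max_treedepth maximum tree depth per iteration.
#' @param step_size initial leapfrog step size (`NULL`: heuristic search).
#' @param brute_force use the aggressive tuning sometimes applied to remove
#'   divergent transitions: target acceptance 0.999 and initial step size
#'   0.001.
#' @return A list of class `"msar_sampler_config"`.
#' @export
sampler_config <- function(chains = 4, iter = 2000, warmup = 1000, seed = 1,
                           target_accept = 0.8, max_treedepth = 10,
                           step_size = NULL, brute_force = FALSE) {
  if (brute_force) {
    target_accept <- 0.999
    step_size <- 0.001
  }
  stopifnot(iter > warmup, warmup >= 0, chains >= 1)
  structure(list(chains = chains, iter = iter, warmup = warmup, seed = seed,
                 target_accept = target_accept, max_treedepth = max_treedepth,
                 step_size = step_size, brute_force = brute_force),
            class = "msar_sampler_config")
}

## one leapfrog step; inv_mass is the diagonal of M^{-1}
leapfrog <- function(lpg, theta, p, eps, inv_mass, grad) {
  p1 <- p + 0.5 * eps * grad
  theta1 <- theta + eps * inv_mass * p1
  lg <- lpg(theta1)
  p2 <- p1 + 0.5 * eps * lg$grad
  list(theta = theta1, p = p2, lp = lg$value, grad = lg$grad)
}

joint_lp <- function(lp, p, inv_mass) lp - 0.5 * sum(inv_mass * p * p)

find_reasonable_epsilon <- function(lpg, theta, inv_mass) {
  eps <- 1
  n <- length(theta)
  p <- rnorm(n) / sqrt(inv_mass)
  lg <- lpg(theta)
  j0 <- joint_lp(lg$value, p, inv_mass)
  step <- leapfrog(lpg, theta, p, eps, inv_mass, lg$grad)
  j1 <- joint_lp(step$lp, step$p, inv_mass)
  if (!is.finite(j1)) j1 <- -Inf
  a <- if (j1 - j0 > log(0.5)) 1 else -1
  for (k in 1:50) {
    eps <- eps * 2^a
    step <- leapfrog(lpg, theta, p, eps, inv_mass, lg$grad)
    j1 <- joint_lp(step$lp, step$p, inv_mass)
    if (!is.finite(j1)) j1 <- -Inf
    if (a * (j1 - j0) <= a * log(0.5)) break
  }
  eps
}

## recursive tree builder (slice variant); returns candidate and U-turn flag
build_tree <- function(lpg, theta, p, grad, lp, log_u, v, depth, eps,
                       inv_mass, j0, env) {
  if (depth == 0L) {
    st <- leapfrog(lpg, theta, p, v * eps, inv_mass, grad)
    j <- joint_lp(st$lp, st$p, inv_mass)
    if (!is.finite(j)) j <- -Inf
    n1 <- as.integer(log_u <= j)
    div <- (log_u - 1000) > j  # divergent transition
    if (div) env$divergent <- TRUE
    env$alpha <- env$alpha + min(1, exp(j - j0))
    env$n_alpha <- env$n_alpha + 1
    return(list(theta_m = st$theta, p_m = st$p, grad_m = st$grad, lp_m = st$lp,
                theta_p = st$theta, p_p = st$p, grad_p = st$grad, lp_p = st$lp,
                theta_c = st$theta, lp_c = st$lp, n = n1, s = !div))
  }
  t1 <- build_tree(lpg, theta, p, grad, lp, log_u, v, depth - 1L, eps,
                   inv_mass, j0, env)
  if (!t1$s) return(t1)
  if (v == -1) {
    t2 <- build_tree(lpg, t1$theta_m, t1$p_m, t1$grad_m, t1$lp_m, log_u, v,
                     depth - 1L, eps, inv_mass, j0, env)
    t1$theta_m <- t2$theta_m; t1$p_m <- t2$p_m
    t1$grad_m <- t2$grad_m; t1$lp_m <- t2$lp_m
  } else {
    t2 <- build_tree(lpg, t1$theta_p, t1$p_p, t1$grad_p, t1$lp_p, log_u, v,
                     depth - 1L, eps, inv_mass, j0, env)
    t1$theta_p <- t2$theta_p; t1$p_p <- t2$p_p
    t1$grad_p <- t2$grad_p; t1$lp_p <- t2$lp_p
  }
  ntot <- t1$n + t2$n
  if (t2$n > 0 && runif(1) < t2$n / ntot) {
    t1$theta_c <- t2$theta_c; t1$lp_c <- t2$lp_c
  }
  dtheta <- t1$theta_p - t1$theta_m
  uturn <- (sum(dtheta * (inv_mass * t1$p_m)) < 0) ||
    (sum(dtheta * (inv_mass * t1$p_p)) < 0)
  t1$n <- ntot
  t1$s <- t2$s && !uturn
  t1
}

## warmup window schedule (init buffer / doubling windows / terminal buffer)
adapt_windows <- function(warmup) {
  if (warmup < 40) {
    return(list(init = max(1, floor(warmup * 0.15)),
                ends = integer(0),
                term_start = max(2, floor(warmup * 0.85))))
  }
  init <- max(20, floor(0.075 * warmup))
  term <- max(25, floor(0.1 * warmup))
  ends <- integer(0)
  w <- 25
  pos <- init
  while (pos + w < warmup - term) {
    pos <- pos + w
    ends <- c(ends, pos)
    w <- 2 * w
  }
  ends <- c(ends, warmup - term)
  list(init = init, ends = unique(ends), term_start = warmup - term)
}

## single-chain NUTS; lpg(theta) -> list(value, grad)
nuts_chain <- function(lpg, theta0, iter, warmup, target_accept = 0.8,
                       max_treedepth = 10, step_size = NULL) {
  n <- length(theta0)
  inv_mass <- rep(1, n)
  theta <- theta0
  lg <- lpg(theta)
  if (!is.finite(lg$value)) {
    stop("nuts: log posterior not finite at the initial value", call. = FALSE)
  }
  eps <- if (is.null(step_size)) find_reasonable_epsilon(lpg, theta, inv_mass)
         else step_size
  ## dual averaging state
  mu <- log(10 * eps); log_eps_bar <- 0; H_bar <- 0
  da_gamma <- 0.05; da_t0 <- 10; da_kappa <- 0.75; da_count <- 0
  win <- adapt_windows(warmup)
  win_draws <- NULL
  draws <- matrix(NA_real_, iter, n)
  lp_hist <- numeric(iter)
  divergences <- logical(iter)
  treedepths <- integer(iter)

  for (it in seq_len(iter)) {
    p0 <- rnorm(n) / sqrt(inv_mass)
    j0 <- joint_lp(lg$value, p0, inv_mass)
    log_u <- j0 - stats::rexp(1)
    env <- new.env()
    env$alpha <- 0; env$n_alpha <- 0; env$divergent <- FALSE
    tm <- theta; tp <- theta
    pm <- p0; pp <- p0
    gm <- lg$grad; gp <- lg$grad
    lm <- lg$value; lpp <- lg$value
    theta_c <- theta; lp_c <- lg$value
    nvalid <- 1L; s <- TRUE; depth <- 0L
    while (s && depth < max_treedepth) {
      v <- if (runif(1) < 0.5) -1 else 1
      if (v == -1) {
        tr <- build_tree(lpg, tm, pm, gm, lm, log_u, v, depth, eps,
                         inv_mass, j0, env)
        tm <- tr$theta_m; pm <- tr$p_m; gm <- tr$grad_m; lm <- tr$lp_m
      } else {
        tr <- build_tree(lpg, tp, pp, gp, lpp, log_u, v, depth, eps,
                         inv_mass, j0, env)
        tp <- tr$theta_p; pp <- tr$p_p; gp <- tr$grad_p; lpp <- tr$lp_p
      }
      if (tr$s && tr$n > 0 && runif(1) < min(1, tr$n / nvalid)) {
        theta_c <- tr$theta_c; lp_c <- tr$lp_c
      }
      nvalid <- nvalid + tr$n
      dtheta <- tp - tm
      s <- tr$s && (sum(dtheta * (inv_mass * pm)) >= 0) &&
        (sum(dtheta * (inv_mass * pp)) >= 0)
      depth <- depth + 1L
    }
    theta <- theta_c
    lg <- lpg(theta)
    draws[it, ] <- theta
    lp_hist[it] <- lg$value
    divergences[it] <- env$divergent
    treedepths[it] <- depth

    if (it <= warmup) {
      ## dual averaging
      da_count <- da_count + 1
      accept_stat <- if (env$n_alpha > 0) env$alpha / env$n_alpha else 0
      H_bar <- (1 - 1 / (da_count + da_t0)) * H_bar +
        (target_accept - accept_stat) / (da_count + da_t0)
      log_eps <- mu - sqrt(da_count) / da_gamma * H_bar
      w_da <- da_count^(-da_kappa)
      log_eps_bar <- w_da * log_eps + (1 - w_da) * log_eps_bar
      eps <- exp(log_eps)
      ## mass-matrix windows
      if (it > win$init && it <= win$term_start) {
        win_draws <- rbind(win_draws, theta)
        if (it %in% win$ends) {
          m <- nrow(win_draws)
          if (m > 4) {
            v_hat <- apply(win_draws, 2, var)
            inv_mass <- (m / (m + 5)) * v_hat + (5 / (m + 5)) * 1e-3
            inv_mass[inv_mass <= 0 | !is.finite(inv_mass)] <- 1e-3
            eps <- find_reasonable_epsilon(lpg, theta, inv_mass)
            mu <- log(10 * eps)
            log_eps_bar <- 0; H_bar <- 0; da_count <- 0
          }
          win_draws <- NULL
        }
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    }
  }
  list(draws = draws, lp = lp_hist, divergences = divergences,
       treedepths = treedepths, step_size = eps, inv_mass = inv_mass)
}

#' Draw from a log-posterior with the built-in NUTS sampler
#'
#' Runs the requested number of chains (serially; per-chain seeds are derived
#' deterministically from `config$seed`), discards warmup, and returns the
#' unconstrained draws with divergence counts.
#'
#' @param posterior an `"msar_posterior"` from [build_log_posterior()], or a
#'   function `theta -> list(value, grad)` together with `n_par`.
#' @param config a [sampler_config()].
#' @param n_par number of parameters (only when `posterior` is a bare
#'   function).
#' @param init optional function returning an initial unconstrained vector.
#' @return List with `draws` (array, post-warmup iterations x chains x
#'   parameters), `divergences` (per chain), `step_size`, `inv_mass`.
#' @export
sample_posterior <- function(posterior, config = sampler_config(),
                             n_par = NULL, init = NULL) {
  if (inherits(posterior, "msar_posterior")) {
    lpg <- posterior$lp_grad
    n_par <- posterior$n_par
    if (is.null(init)) init <- posterior$init
  } else {
    lpg <- posterior
    if (is.null(n_par)) stop("sample_posterior: n_par required", call. = FALSE)
    if (is.null(init)) init <- function() rnorm(n_par, 0, 0.5)
  }
  keep <- config$iter - config$warmup
  draws <- array(NA_real_, c(keep, config$chains, n_par))
  div <- integer(config$chains)
  stepsizes <- numeric(config$chains)
  inv_mass <- NULL
  chain_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, config$chains))
  for (ch in seq_len(config$chains)) {
    res <- with_seed(chain_seeds[ch], {
      th0 <- init()
      ## retry a few times if the start is degenerate
      tries <- 0
      while (!is.finite(lpg(th0)$value) && tries < 20) {
        th0 <- init(); tries <- tries + 1
      }
      nuts_chain(lpg, th0, config$iter, config$warmup,
                 target_accept = config$target_accept,
                 max_treedepth = config$max_treedepth,
                 step_size = config$step_size)
    })
    draws[, ch, ] <- res$draws[(config$warmup + 1):config$iter, ]
    div[ch] <- sum(res$divergences[(config$warmup + 1):config$iter])
    stepsizes[ch] <- res$step_size
    inv_mass <- res$inv_mass
  }
  list(draws = draws, divergences = div, step_size = stepsizes,
       inv_mass = inv_mass, config = config)
}
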