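test_that("selection rules follow the interval and thresholding definitions", {
  s <- list(mean = c(0.5, 0.12, 0.05), lower = c(0.1, -0.1, -0.2),
            upper = c(0.9, 0.2, 0.3))
  expect_equal(selection_decision(s, "ci95"), c(TRUE, FALSE, FALSE))
  expect_equal(selection_decision(s, "thr_0.10"), c(TRUE, TRUE, FALSE))
  expect_equal(selection_decision(s, "thr_0.15"), c(TRUE, FALSE, FALSE))
  ## interval straddling zero is never selected under ci95, whatever the mean
  s2 <- list(mean = 5, lower = -0.1, upper = 0.2)
  expect_false(selection_decision(s2, "ci95"))
  expect_error(selection_decision(s, "bonferroni"), "arg")
})

test_that("power and type-I error count selections over replications", {
  truth <- c(0.5, 0)
  mk <- function(sel_nz, sel_z) {
    ## intervals excluding zero encode a selection
    replication_record(mean = c(0.5, 0),
                       lower = c(if (sel_nz) 0.1 else -0.1,
                                 if (sel_z) 0.05 else -0.1),
                       upper = c(0.9, if (sel_z) 0.2 else 0.1),
                       truth = truth)
  }
  reps <- c(replicate(3, mk(TRUE, TRUE), simplify = FALSE),
            replicate(17, mk(TRUE, FALSE), simplify = FALSE))
  pt <- power_and_type1(reps, "ci95")
  expect_equal(pt$power, 1)
  expect_equal(pt$type1, 3 / 20)
  expect_equal(pt$M, 20)
  ## estimates at zero with intervals containing zero: type-I is 0
  reps0 <- replicate(5, mk(TRUE, FALSE), simplify = FALSE)
  expect_equal(power_and_type1(reps0, "ci95")$type1, 0)
  ## non-converged replications are excluded
  bad <- mk(FALSE, TRUE); bad$converged <- FALSE
  expect_equal(power_and_type1(c(reps, list(bad)), "ci95")$M, 20)
  expect_warning(power_and_type1(list(bad), "ci95"), "no converged")
})

test_that("coin-flip decisions drive both rates to one half", {
  set.seed(51)
  truth <- c(0.5, -0.5, 0, 0)
  reps <- lapply(1:600, function(m) {
    sel <- runif(4) < 0.5
    replication_record(mean = ifelse(sel, 1, 0),
                       lower = ifelse(sel, 0.5, -1), upper = ifelse(sel, 1.5, 1),
                       truth = truth)
  })
  pt <- power_and_type1(reps, "ci95")
  expect_equal(pt$power, 0.5, tolerance = 0.06)
  expect_equal(pt$type1, 0.5, tolerance = 0.06)
})

test_that("widening intervals weakly decreases both ci95 rates", {
  set.seed(52)
  truth <- c(0.5, 0)
  mk <- function(width) {
    m <- rnorm(2, truth, 0.3)
    replication_record(mean = m, lower = m - width, upper = m + width,
                       truth = truth)
  }
  for (w in c(0.2, 0.5, 1)) {
    assign(paste0("r", w), lapply(1:200, function(i) mk(w)))
  }
  set.seed(52); a <- power_and_type1(lapply(1:200, function(i) mk(0.2)), "ci95")
  set.seed(52); b <- power_and_type1(lapply(1:200, function(i) mk(0.6)), "ci95")
  expect_lte(b$power, a$power)
  expect_lte(b$type1, a$type1)
})

test_that("pooled rate equals the coefficient-weighted mean of per-coefficient rates", {
  set.seed(53)
  truth <- c(0.5, -0.5, 0.5, 0, 0)
  reps <- lapply(1:50, function(m) {
    mm <- rnorm(5, truth, 0.4)
    replication_record(mean = mm, lower = mm - 0.3, upper = mm + 0.3,
                       truth = truth)
  })
  pt <- power_and_type1(reps, "ci95")
  pc <- pt$per_coef
  expect_equal(pt$power, mean(pc$rate[pc$role == "power"]))
  expect_equal(pt$type1, mean(pc$rate[pc$role == "type1"]))
})

test_that("accuracy metrics reproduce hand arithmetic", {
  truth <- c(0.5, 0)
  reps <- replicate(10, replication_record(mean = c(0, 0), lower = c(-0.1, -0.1),
                                           upper = c(0.1, 0.1), truth = truth),
                    simplify = FALSE)
  a <- accuracy_metrics(reps)
  expect_equal(a$bias, c(-0.5, 0))
  expect_equal(a$rel_bias, c(-1, NA))
  expect_equal(a$rmse, c(0.5, 0))
  expect_equal(a$abs_bias, c(0.5, 0))
  expect_equal(a$coverage, c(0, 1))
  ## estimates equal to truth: all biases zero
  reps2 <- replicate(4, replication_record(mean = truth, lower = truth - 0.1,
                                           upper = truth + 0.1, truth = truth),
                     simplify = FALSE)
  a2 <- accuracy_metrics(reps2)
  expect_true(all(a2$bias == 0) && all(a2$rmse == 0))
  expect_equal(a2$coverage, c(1, 1))
  ## RMSE dominates |bias|
  set.seed(54)
  reps3 <- lapply(1:40, function(i) {
    m <- rnorm(2, truth, 0.3)
    replication_record(m, m - 1, m + 1, truth)
  })
  a3 <- accuracy_metrics(reps3)
  expect_true(all(a3$rmse >= abs(a3$bias) - 1e-12))
})

test_that("admissible bands match the binomial interval arithmetic", {
  b <- admissible_bands(power = 0.85, type1 = 0.05, M = 200)
  expect_equal(b$type1_band, c(0.0198, 0.0802), tolerance = 1e-3)
  expect_equal(1.96 * sqrt(0.05 * 0.95 / 200), 0.0302, tolerance = 1e-3)
  expect_true(b$power_ok); expect_true(b$type1_ok)
  ## closed-interval boundary convention
  expect_false(admissible_bands(power = 0.79)$power_ok)
  expect_true(admissible_bands(power = 0.80)$power_ok)
  ## band shrinks to {0.05} as M grows
  b_inf <- admissible_bands(M = 1e12)$type1_band
  expect_equal(b_inf, c(0.05, 0.05), tolerance = 1e-5)
})

test_that("metrics table aggregates all three rules", {
  set.seed(55)
  truth <- c(0.5, -0.5, 0, 0)
  reps <- lapply(1:30, function(i) {
    m <- rnorm(4, truth, 0.1)
    replication_record(m, m - 0.25, m + 0.25, truth)
  })
  mt <- metrics_table(reps)
  expect_equal(nrow(mt$rates), 3)
  expect_true(all(mt$rates$power >= 0 & mt$rates$power <= 1))
  expect_true(all(mt$rates$type1 >= 0 & mt$rates$type1 <= 1))
  expect_equal(mt$M_converged, 30)
  expect_output(print(mt), "converged replications")
})
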