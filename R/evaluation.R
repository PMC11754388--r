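## Replication-level evaluation: selection rules, power and type-I error,
## bias/accuracy metrics, and the admissible bands used to judge them.

#' Selection decision for one coefficient summary
#'
#' `"ci95"` selects when the 95\% credible interval excludes zero;
#' `"thr_0.10"` / `"thr_0.15"` select when the absolute point estimate
#' (posterior mean) strictly exceeds the cutoff.
#'
#' @param summary list or data.frame with elements/columns `mean`, `lower`,
#'   `upper` (vectors over coefficients).
#' @param rule one of `"ci95"`, `"thr_0.10"`, `"thr_0.15"`.
#' @param estimate which point estimate the thresholding rules use
#'   (`"mean"`, or `"mode"` if a `mode` element is present).
#' @return Logical vector of selections.
#' @export
selection_decision <- function(summary, rule = c("ci95", "thr_0.10", "thr_0.15"),
                               estimate = "mean") {
  rule <- match.arg(rule)
  if (rule == "ci95") {
    return(!(summary$lower < 0 & summary$upper > 0))
  }
  cut <- if (rule == "thr_0.10") 0.1 else 0.15
  est <- summary[[estimate]]
  if (is.null(est)) stop("selection_decision: estimate '", estimate,
                         "' not available", call. = FALSE)
  abs(est) > cut
}

#' Build a replication record
#'
#' @param mean,lower,upper posterior summaries of the slope vector.
#' @param truth true slope vector.
#' @param converged did the replication satisfy the R-hat rule.
#' @param mode optional posterior modes.
#' @return List of class `"msar_replication"`.
#' @export
replication_record <- function(mean, lower, upper, truth, converged = TRUE,
                               mode = NULL) {
  stopifnot(length(mean) == length(truth), length(lower) == length(truth),
            length(upper) == length(truth))
  structure(list(mean = mean, lower = lower, upper = upper, truth = truth,
                 converged = converged, mode = mode),
            class = "msar_replication")
}

converged_only <- function(replications) {
  keep <- vapply(replications, function(r) isTRUE(r$converged), logical(1))
  replications[keep]
}

#' Power and type-I error over replications
#'
#' Averages the selection indicator over the converged replications,
#' separately for the truly non-zero coefficients (power) and the truly zero
#' coefficients (type-I error), per coefficient and pooled.
#'
#' @param replications list of [replication_record()]s.
#' @param rule selection rule (see [selection_decision()]).
#' @param estimate point estimate for the thresholding rules.
#' @return List with `power`, `type1` (pooled rates), `per_coef` data.frame,
#'   and `M` (number of converged replications used). If nothing converged,
#'   returns `NULL` with a warning.
#' @export
power_and_type1 <- function(replications, rule = "ci95", estimate = "mean") {
  reps <- converged_only(replications)
  if (!length(reps)) {
    warning("power_and_type1: no converged replications")
    return(NULL)
  }
  truth <- reps[[1]]$truth
  sel <- vapply(reps, function(r) selection_decision(r, rule, estimate),
                logical(length(truth)))
  sel <- matrix(sel, nrow = length(truth))
  rate <- rowMeans(sel)
  nonzero <- truth != 0
  list(power = if (any(nonzero)) mean(sel[nonzero, , drop = FALSE]) else NA_real_,
       type1 = if (any(!nonzero)) mean(sel[!nonzero, , drop = FALSE]) else NA_real_,
       per_coef = data.frame(truth = truth, rate = rate,
                             role = ifelse(nonzero, "power", "type1")),
       M = length(reps))
}

#' Bias, accuracy and coverage over replications
#'
#' Per coefficient (converged replications only): `bias = mean(est) - truth`,
#' `rel_bias = bias / truth` (reported as `NA` where the truth is zero),
#' `abs_bias = mean(|est - truth|)`, `rmse = sqrt(mean((est - truth)^2))`,
#' and `coverage` = fraction of intervals containing the truth.
#'
#' @param replications list of [replication_record()]s.
#' @return data.frame with one row per coefficient, plus attribute `M`.
#' @export
accuracy_metrics <- function(replications) {
  reps <- converged_only(replications)
  if (!length(reps)) {
    warning("accuracy_metrics: no converged replications")
    return(NULL)
  }
  truth <- reps[[1]]$truth
  est <- vapply(reps, function(r) r$mean, numeric(length(truth)))
  est <- matrix(est, nrow = length(truth))
  lo <- matrix(vapply(reps, function(r) r$lower, numeric(length(truth))),
               nrow = length(truth))
  hi <- matrix(vapply(reps, function(r) r$upper, numeric(length(truth))),
               nrow = length(truth))
  bias <- rowMeans(est) - truth
  out <- data.frame(
    truth = truth,
    mean_est = rowMeans(est),
    bias = bias,
    rel_bias = ifelse(truth != 0, bias / truth, NA_real_),
    abs_bias = rowMeans(abs(est - truth)),
    rmse = sqrt(rowMeans((est - truth)^2)),
    coverage = rowMeans(lo <= truth & truth <= hi)
  )
  attr(out, "M") <- length(reps)
  out
}

#' Admissible-band flags for power and type-I error rates
#'
#' Power is admissible in `[0.8, 1]` (closed). The type-I band is
#' \eqn{0.05 \pm 1.96\sqrt{0.05\cdot 0.95/M}}; at `M = 200` this is
#' approximately `[0.02, 0.08]`.
#'
#' @param power,type1 rates (either may be `NULL`).
#' @param M number of replications behind the type-I rate.
#' @return List with `power_ok`, `type1_ok` and the `type1_band` used.
#' @export
admissible_bands <- function(power = NULL, type1 = NULL, M = 200) {
  half <- 1.96 * sqrt(0.05 * 0.95 / M)
  band <- c(0.05 - half, 0.05 + half)
  list(
    power_ok = if (is.null(power)) NA else power >= 0.8 & power <= 1,
    type1_ok = if (is.null(type1)) NA else type1 >= band[1] & type1 <= band[2],
    type1_band = band
  )
}

#' Full metrics table for one (design cell, prior) combination
#'
#' Combines [power_and_type1()] under the three selection rules,
#' [accuracy_metrics()], and [admissible_bands()].
#'
#' @param replications list of [replication_record()]s.
#' @return List of class `"msar_metrics"` with elements `rates` (data.frame
#'   over rules), `accuracy`, `bands`, `M_converged`, `M_total`.
#' @export
metrics_table <- function(replications) {
  rules <- c("ci95", "thr_0.10", "thr_0.15")
  pt <- lapply(rules, function(r) power_and_type1(replications, r))
  ok <- !vapply(pt, is.null, logical(1))
  rates <- data.frame(
    rule = rules[ok],
    power = vapply(pt[ok], function(x) x$power, numeric(1)),
    type1 = vapply(pt[ok], function(x) x$type1, numeric(1))
  )
  acc <- accuracy_metrics(replications)
  M <- if (any(ok)) pt[ok][[1]]$M else 0L
  bands <- lapply(seq_len(nrow(rates)), function(i) {
    admissible_bands(rates$power[i], rates$type1[i], M = max(M, 1))
  })
  structure(list(rates = rates, accuracy = acc, bands = bands,
                 M_converged = M, M_total = length(replications)),
            class = "msar_metrics")
}

#' @export
print.msar_metrics <- function(x, ...) {
  cat(sprintf("Metrics over %d/%d converged replications\n",
              x$M_converged, x$M_total))
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Panel plot of power / type-I rates across design cells
#'
#' Simple base-graphics rendering of rate-versus-condition curves with the
#' admissible band shaded.
#'
#' @param rates data.frame with columns `condition`, `prior`, `rate`.
#' @param kind `"power"` (band `[0.8, 1]`) or `"type1"` (band
#'   `[0.02, 0.08]`).
#' @param M replication count for the type-I band.
#' @param ... passed to `matplot`.
#' @importFrom graphics rect
#' @export
plot_rate_panel <- function(rates, kind = c("power", "type1"), M = 200, ...) {
  kind <- match.arg(kind)
  priors <- unique(rates$prior)
  conds <- sort(unique(rates$condition))
  mat <- sapply(priors, function(p) {
    sapply(conds, function(cc) {
      v <- rates$rate[rates$prior == p & rates$condition == cc]
      if (length(v)) mean(v) else NA_real_
    })
  })
  matplot(conds, mat, type = "b", pch = seq_along(priors), lty = 1,
          ylim = c(0, 1), xlab = "condition", ylab = kind, ...)
  band <- if (kind == "power") c(0.8, 1) else admissible_bands(M = M)$type1_band
  rect(min(conds) - 1e6, band[1], max(conds) + 1e6, band[2],
       col = grDevices::adjustcolor("grey", 0.3), border = NA)
  legend("topleft", legend = priors, pch = seq_along(priors), lty = 1,
         bty = "n", cex = 0.8)
  invisible(mat)
}
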