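# msarreg

Bayesian estimation of **two-level Markov-switching autoregressive (MSAR(1))
models** for intensive longitudinal data, with **regularizing priors** on the
predictors of the regime-switching process.

## The problem

Panel studies in psychology and education increasingly collect many repeated
measurements per person (daily affect ratings, session-by-session alliance
scores, ...). A natural model lets each individual's series
$\eta_{y,it}$ alternate between two latent regimes — e.g. a stable baseline
and a drift regime — governed by a hidden two-state Markov chain
$S_{it}$:

$$\eta_{y,it} \mid S_{it}=s \;=\; A_s + B_s\,\eta_{y,it-1} +
\gamma\,\eta_{z,it} + \epsilon_{it},\qquad A_1 = B_1 = 0 .$$

The scientific question is usually *which predictors drive the switching*.
The chain starts in state 1, returns from state 2 with fixed probability
$p_{21}$, and stays in state 1 with probability
$\mathrm{logistic}(\tilde\eta_{it})$, where

$$\tilde\eta_{it} = \underbrace{\beta_0 + \beta_x^\top \eta_{x,i} +
\epsilon_{0i}}_{\text{random intercept}} \;+\;
\underbrace{\beta_z \eta_{z,it} + (\beta_{xz}^\top\eta_{x,i})\,
\eta_{z,it}}_{\text{time-varying (optional)}} \;+\;
\underbrace{\beta_y^\top \eta_{y,it-1} + \beta_{xy}^\top(\eta_{x,i} \otimes
\eta_{y,it-1})}_{\text{lag feedback (optional)}} .$$

With many candidate predictors the slope vector $\beta^*$ is "nearly black"
(mostly zeros), so it receives one of four **regularizing prior families** —
ridge, Bayesian Lasso, adaptive Bayesian spike-and-slab Lasso, or the
regularized horseshoe — each with named sensitivity presets
(`list_prior_presets()`).

Estimation marginalizes the discrete chain with the **Hamilton forward
filter**, making the posterior differentiable, and samples it with a
built-in gradient-based NUTS sampler (the likelihood gradient is an analytic
reverse-mode pass through the filter recursion, in C++). A replication
harness computes the method-comparison metrics: convergence and precision
rates, power and type-I error under credible-interval and thresholding
rules, bias, RMSE, coverage, and their admissible bands.

## Worked example

Simulate a time-invariant design (50 individuals, 25 occasions, 5 candidate
predictors of which two are active: $\beta^* = (0.5, -0.5, 0, 0, 0)$) and
fit it under the standard-normal ridge preset:

```r
library(msarreg)
design <- sim1_design(N = 50, T = 25, P = 5, zero_rate = 0.5, seed = 42)
d <- generate_sim1(design)
design_snr(design)       # 0.0816 -- a deliberately hard, low-signal regime
fit <- msar(d, prior = "Ridge-0", chains = 2, iter = 1000, warmup = 500, seed = 42)
print(fit)
```

```
Two-level Markov-switching AR(1) fit
  data: N = 50, T = 25, P = 5 transition slopes; prior: Ridge-0
  sampler: 2 chains x 1000 iterations (500 warmup); 0 divergences
max R-hat = 1.015 (converged); min ESS = 195; divergences = 0
precision: ESS>100: yes, ESS>400: no, ESS>1000: no 

Transition slopes (posterior mean [95% CI]):
  beta[1]     0.708 [ 0.065,  1.403]
  beta[2]    -1.126 [-1.904, -0.350]
  beta[3]     0.397 [-0.355,  1.103]
  beta[4]    -0.160 [-0.894,  0.625]
  beta[5]     0.011 [-0.669,  0.663]
```

Reading the output: all R-hat are below the 1.1 convergence threshold; the
two truly active slopes are selected by the 95% interval rule (their
intervals exclude 0) with the expected signs, while the three null slopes
are not selected. At this sample size and signal-to-noise ratio (0.08), the
posterior intervals are wide — this is the regime the simulation designs
deliberately probe. `summary(fit)` gives the full table (also `coef()`,
`residuals()` for one-step standardized residuals, `fitted()` for filtered
state probabilities, `plot(fit)`, `posterior_mode(fit)`).

Replication studies over a design grid:

```r
res <- replicate_study(sim1_design(N = 50, T = 25, P = 5, seed = 1),
                       prior = "Ridge-0", M = 20)
res$rates$convergence_rate     # share of replications with all R-hat < 1.1
res$metrics$rates              # power / type-I under ci95, |b|>0.1, |b|>0.15
```

`run_grid()` sweeps cells × priors and writes per-cell metrics, a combined
report and a manifest; `scripts/msar-cli.R` exposes `simulate`, `fit`,
`evaluate`, `grid` and `priors` subcommands for shell use.

## Package layout

* `R/model-core.R` — parameter containers, transition predictor, densities
* `R/forward-filter.R`, `src/msar_filter.cpp` — Hamilton filter (+ gradient)
* `R/priors.R` — prior families, presets, density curves
* `R/simulate.R` — study designs, generators, SNR
* `R/posterior.R`, `R/hmc.R`, `R/diagnostics.R` — posterior, NUTS, R-hat/ESS
* `R/msar.R` — the `msar()` fitting function and S3 methods
* `R/evaluation.R`, `R/harness.R` — selection rules, metrics, grid runner
* `vignettes/msarreg-methods.Rmd` — model, priors, design choices, limits
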