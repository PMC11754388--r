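---
title: "Regularized Bayesian Markov-switching AR(1) models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized Bayesian Markov-switching AR(1) models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`msarreg` fits a two-level Markov-switching autoregressive model of order 1
for intensive longitudinal data: many occasions $t = 1, \dots, T$ on each of
$N$ individuals. A latent two-state chain $S_{it} \in \{1, 2\}$ switches the
dynamics of a univariate (in the fitted models) latent series
$\eta_{y,it}$:

$$\eta_{y,it} \mid S_{it} = s \;=\; A_s + B_s\,\eta_{y,it-1} +
\gamma\,\eta_{z,it} + \epsilon_{it}, \qquad
\epsilon_{it} \sim N(0, \sigma_\epsilon^2),$$

with the state-1 identification constraints $A_1 = B_1 = 0$. State 1 is
therefore a white-noise regime around the covariate effect, and state 2 an
AR(1) regime with its own level. Because $A_2$ carries a positive
(half-normal) prior and every individual starts in state 1, the state labels
are anchored and no post-hoc relabeling is needed.

The chain starts in state 1 ($S_{i1} = 1$), stays there with probability

$$p_{it,11} = \mathrm{logistic}(\tilde\eta_{it}), \qquad
\tilde\eta_{it} = \mu_{0i} + \mu_{1it} + \mu_{2,it-1},$$

and returns from state 2 with a fixed probability `p21` (default 0.05; it is
part of the generating assumptions, not an estimated parameter). The
transition predictor decomposes into

* $\mu_{0i} = \beta_0 + \beta_x^\top \eta_{x,i} + \epsilon_{0i}$ — a random
  intercept with between-level covariates,
  $\epsilon_{0i} \sim N(0, \sigma_{\epsilon_0}^2)$;
* $\mu_{1it} = \beta_z \eta_{z,it} + (\beta_{xz}^\top \eta_{x,i})\eta_{z,it}$
  — an optional time-varying covariate with cross-level interactions;
* $\mu_{2,it-1} = \beta_y^\top \eta_{y,it-1} + \beta_{xy}^\top(\eta_{x,i}
  \otimes \eta_{y,it-1})$ — an optional feedback of the lagged series, zero
  at $t = 1$ where no lag exists.

The stacked slope vector $\beta^* = (\beta_x, \beta_z, \beta_{xz}, \beta_y,
\beta_{xy})$ of length $P$ is the estimand of interest: which predictors
drive the regime switching. A measurement layer (factor loadings with
item-level error) exists in the types and density functions; the shipped
designs and the sampler use unit loadings with zero measurement error, so
observed items coincide with the latent variables.

## Marginalized likelihood

Gradient-based samplers cannot handle the discrete $S_{it}$, so the chain is
marginalized out with the Hamilton forward filter. Writing $\xi_{sit} =
P(S_{it} = s \mid \eta_{y,i,1:t})$, the filter alternates a chain-prediction
step with a Bayes update, and accumulates the one-step predictive
log-densities into the marginal log-likelihood. Two conventions matter:

* **Initialization.** $\xi_{1,i1} = 1$, matching the assumption that every
  individual starts in state 1.
* **Conditioning at $t = 1$.** No marginal distribution is imposed on
  $\eta_{y,i1}$; the likelihood conditions on the first occasion and sums
  predictive terms over $t = 2, \dots, T$. This is the only reading
  consistent with fixing $\xi$ at $t = 1$ and supplying no initial density,
  and it is documented and tested (`per_time_loglik[, 1]` is `NA`). The
  simulator correspondingly generates the first occasion from the state-1
  model with a zero pre-sample value; since the filter conditions on it,
  this choice cannot bias estimation.
* **Timing.** The transition from $t-1$ to $t$ uses the predictor indexed
  $t$: covariates enter contemporaneously ($\eta_{z,it}$), the lagged series
  at $t - 1$.

All accumulation is in log space (log-sum-exp). `forward_loglik()` is the
reference R implementation for any $K$; a C++ twin used by the sampler
additionally returns the analytic gradient, obtained by a hand-derived
reverse-mode (adjoint) pass through the recursion. An independent oracle,
`brute_force_loglik()`, enumerates all $2^{T-1}$ state paths and is compared
against the filter to $10^{-8}$ in the tests; it refuses $T > 15$.

Two numerical guards in the C++ path: the stay probability is clamped to
$[10^{-12}, 1 - 10^{-12}]$ so the two-component mixture never degenerates
exactly (the effect on the log-likelihood is below double precision for all
realistic predictors), and a parameter point whose predictive density
underflows returns $-\infty$, which the sampler treats as an ordinary
rejection.

## Priors

The slope vector $\beta^*$ receives one of four regularizing families
(`msar_prior()`), all centered at zero:

| family | hierarchy | default preset |
|---|---|---|
| ridge | $\beta_p \sim N(0, \sigma_\eta^2/\lambda)$, fixed $\lambda$ | `Ridge-0`: standard normal |
| B-Lasso | $\beta_p \sim \mathrm{Laplace}(0, \sigma_\eta/\lambda)$, $\lambda \sim C^+(0, 2.5)$ | `B-Lasso` |
| aBSS-Lasso | $\beta_p = \bar\beta_p \nu_p$, $\bar\beta_p \sim \mathrm{Laplace}(0, \sigma_\eta/\lambda_p)$, $\nu_p \sim \mathrm{Beta}(\tfrac12, \tfrac12)$, $\lambda_p \sim C^+(0, 2.5)$ | `ABSS-Lasso-0` |
| reg. horseshoe | $\beta_p \sim N(0, \tilde\lambda_p^2\tau^2)$, $\tilde\lambda_p^2 = \frac{c^2\lambda_p^2}{c^2 + \tau^2\lambda_p^2}$, $\lambda_p \sim C^+(0,1)$, $\tau \sim t^+_{\nu_0}(0, \tau_0^2)$, $c^2 \sim I\Gamma(\nu_c/2, \nu_c s_c^2/2)$ | `reg-HS-0` |

The spike-and-slab construction is the *continuous* product form: the
inclusion weight $\nu_p$ multiplies a Laplace-distributed raw coefficient,
with the spike constant at zero. A discrete Dirac mixture is deliberately
out of scope — it is incompatible with gradient-based sampling.

Design choices where the sources were ambiguous, adopted once and exposed as
options:

* **$\tau_0$ rule.** The global-scale default is $\tau_0 = \pi/\sqrt{3NT}$,
  which follows from $\tau_0 = \frac{P_0}{P - P_0}\frac{\sigma_\eta}{\sqrt{NT}}$
  with a 50% prior guess of non-zero coefficients and the logistic residual
  scale $\sigma_\eta = \pi/\sqrt3$. The alternative $\pi/\sqrt{NT}$ is
  available as an override, and the `reg-HS-2` preset uses $2/\sqrt{NT}$
  with $t^+_3$ tails.
* **Lasso scale linkage.** For the Lasso families $\sigma_\eta$ defaults to
  the model's $\sigma_{\epsilon_0}$ (so the penalty is calibrated to the
  random-intercept scale); the presets `ABSS-Lasso-1/2` and `B-Lasso` fix it
  at 1 or 2.
* **State-2 AR slope.** $B_2$ gets a standard normal prior (the multivariate
  convention); a Beta prior on the stationary range is mentioned in the
  literature without stated hyperparameters and is not implemented.
* **$\gamma$.** The within-level covariate effect has no catalog entry; it
  receives a standard normal, consistent with the treatment of the other
  within-level slopes.

Everything else gets weakly informative baselines: half-Cauchy(0, 2.5) for
standard deviations, half-normal(0, 10) for $\beta_0$ and $A_2$ (scale = SD),
LKJ(4) for the residual correlation when $K > 1$, half-normal(0, 1) for free
loadings. Each fixed-hyperparameter marginal prior is verified by quadrature
to integrate to 1, and the normal–exponential mixture representation of the
Laplace is checked pointwise.

## Posterior and sampler

`build_log_posterior()` assembles log prior + marginal log-likelihood +
transform Jacobians on an unconstrained parameterization:

* positive parameters ($\beta_0$, $A_2$, $\sigma_\epsilon$,
  $\sigma_{\epsilon_0}$, penalties, $\tau$, $c^2$) are sampled on the log
  scale with Jacobian corrections; reported densities are over the
  constrained variables;
* the random intercepts are non-centered:
  $\epsilon_{0i} = \sigma_{\epsilon_0} r_i$, $r_i \sim N(0, 1)$;
* Lasso coefficients are non-centered Laplace draws
  ($\bar\beta_p = b_p\,\sigma_\eta/\lambda_p$, $b_p \sim
  \mathrm{Laplace}(0,1)$), and horseshoe coefficients non-centered normal
  draws scaled by $\tilde\lambda_p \tau$ — both needed for the funnel
  geometry of hierarchical scales;
* inclusion probabilities are sampled on the logit scale with a Beta prior.

The gradient of the likelihood comes from the C++ adjoint pass; prior and
Jacobian gradients are analytic. The full gradient is validated against
central finite differences for every family and both transition structures
(relative tolerance $10^{-5}$ in the tests; observed errors are orders of
magnitude smaller). The Laplace component is non-differentiable at exactly
zero; as in standard practice the subgradient is used and the event has
measure zero along any trajectory.

Sampling uses the package's own No-U-Turn sampler: recursive doubling with a
slice variable, dual-averaging step-size adaptation toward a target
acceptance statistic (default 0.8), and a diagonal mass matrix re-estimated
in expanding warmup windows. Divergent transitions (energy error > 1000) are
counted and reported but do not invalidate a run unless the R-hat rule
fails. A `brute_force` control preset (target acceptance 0.999, initial step
size 0.001) mirrors the aggressive tuning sometimes used to suppress
divergences. Defaults are 4 chains of 2000 iterations with 1000 warmup.
Chains run serially; per-chain seeds derive deterministically from the fit
seed, so results are exactly reproducible.

Initial values are drawn from mildly scaled distributions around the prior
center (positive parameters near 1); a degenerate start is redrawn up to 20
times. Variational pre-initialization is out of scope.

## Diagnostics and summaries

R-hat and ESS use the rank-normalized split-chain definitions (bulk and
folded R-hat, Geyer-truncated autocorrelation ESS). The convergence rule is
the classical threshold: a fit converges when **all** monitored parameters —
slopes, within-level parameters, random intercepts and prior auxiliaries —
have R-hat < 1.1. Precision flags record whether all ESS exceed 100, 400 and
1000. `convergence_and_precision()` turns per-replication diagnostics into
rates, and every downstream metric is computed over converged replications
only.

`summarize()` reports posterior mean, SD and a 95% equal-tailed interval by
default. The interval type for the replication rule is not pinned down by
the sources; equal-tailed is the default and highest-posterior-density
intervals are available (`interval = "hpd"`). `posterior_mode()` maximizes
the joint log posterior from the posterior-mean start — under these priors
the mode corresponds to the frequentist penalized estimate.

## Simulators

`generate_sim1()` reproduces the time-invariant study: covariates
$\eta_x \sim N_P(0, \Phi)$ with unit variances and 0.3 correlations, slopes
alternating $+0.5, -0.5$ with the rest exactly zero (non-zero count
$\lfloor P(1 - \text{zero rate})\rfloor$, validated against the 12-of-25
cell), $\beta_0 = 3$, $A_2 = 3$, $B_2 = 0.8$, $\gamma = 0.5$,
$\sigma_\epsilon = 0.25$, return probability 0.05. `generate_sim2()` adds
the time-varying component: $\eta_{z,it} \sim N(0, 1)$ i.i.d., $\beta_z =
0.5$, seven interaction slots. Two values the sources do not print were
fixed once:

* $\sigma_{\epsilon_0} = 1$ for the time-invariant design — the unique value
  consistent with the printed design signal-to-noise ratio at $P = 5$ given
  $\sigma_s^2 = \pi^2/3$;
* $\sigma_s^2 = \pi^2/3$, the standard residual variance of the latent
  logistic scale, as the "noise" term of the SNR denominator; and unit
  variance for $\eta_z$ (it is centered, its scale is not printed).

The printed interaction-slope vector for the time-varying design has eight
entries for seven slots; the three non-zeros $(0.5, -0.5, 0.5)$ are placed
in the last three interaction slots, and $T \in \{30, \dots, 70\}$ is
supported. This placement is a documented reading, not asserted as the
original intent. The design SNR at $P = 15$ and $P = 25$ printed in the
sources is not reproducible under the stated formula with any zero rate of
the grid; those two values are therefore not used as checks (the $P = 5$
value 0.08 reproduces exactly).

The generators emulate the *study* conditions: exact sparsity, moderate
effects, Gaussian covariates, no missingness, error-free measurement, a
known start state. They do not emulate features of real intensive
longitudinal data such as missing observations, ordinal items, measurement
error or more than two regimes — so passing tests demonstrate correctness of
the machinery under the stated generating process, not robustness to those
complications.

## Evaluation harness

`selection_decision()` implements three rules per coefficient: the 95%
credible-interval rule (select when 0 is outside the interval) and the
thresholding rules $|\hat\beta_p| > 0.1$ and $> 0.15$ with strict
inequality, applied to the posterior mean (the posterior mode is available
by flag). Power averages the indicator over truly non-zero coefficients,
type-I error over true zeros, always across converged replications.
`accuracy_metrics()` adds bias, relative bias (undefined — reported absent —
at zero truths), absolute bias, RMSE and coverage. `admissible_bands()`
flags power in $[0.8, 1]$ and type-I error inside
$0.05 \pm 1.96\sqrt{0.05 \cdot 0.95/M}$, which reproduces $[0.02, 0.08]$ at
$M = 200$. Panel averages are averages of *rates* (the alternative —
averaging estimates before thresholding — is documented but not used).

## Problem sizes used by the shipped checks

The full study grid (54 cells × 4 priors × 200 replications) is a
cluster-scale computation. The package's own checks run at desk scale,
chosen once as representative:

* filter–oracle equivalence on 100 randomized draws at $N = 3$, $T = 10$;
* one full-scale recovery run at $N = 100$, $T = 50$, $P = 5$ under the
  ridge preset with 4 × (1000 + 1000) draws;
* replication studies at $M = 20$ on two reduced cells — a small
  time-invariant cell ($N = 20$, $T = 10$, $P = 5$) and a reduced
  time-varying cell ($N = 25$, $T = 30$, $P = 15$) — with 2 shorter chains
  per fit and a tree-depth cap of 8, sizes at which the ridge posterior is
  well explored;
* generator fidelity on simulations with at least $10^5$ transitions.

Seeds for all of these are fixed in the test files; `run_grid()` scales the
same machinery to arbitrary cells and replication counts
(per-replication seeds are base seed + replication index).

## Known limitations

* The sampler handles $K = 1$ (univariate within-level series); $K > 1$ is
  supported in the types, densities and reference filter only.
* Two regimes; the return probability is fixed, not estimated.
* No missing data, no categorical items, and the measurement layer is not
  part of the sampled posterior (the shipped designs are error-free).
* Interval-based selection at a single replication is a stochastic event
  (per-coefficient type-I is about 5% by construction), so single-dataset
  selection results should be read accordingly.
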