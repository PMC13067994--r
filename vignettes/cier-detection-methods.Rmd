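---
title: "Detecting careless responding in intensive longitudinal data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting careless responding in intensive longitudinal data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ciermix)
```

## The problem

Ecological momentary assessment (EMA) asks respondents to answer short
Likert-scale questionnaires several times a day for days or weeks. The
burden of that schedule invites careless/insufficient-effort responding
(C/IER): answering without processing item content. Even modest C/IER rates
distort estimated dynamics and correlations, so occasion-level detection —
which observations, not which persons, are careless — is the target.

`ciermix` implements a confirmatory two-state mixture of item response
models for exactly this setting, combined with a continuous-time latent
Markov model for how respondents move between attentive and careless
states, and a simulation harness that quantifies when detection can and
cannot be trusted.

## The measurement mixture

Each respondent-by-occasion observation is treated as coming from one of
two latent states.

**Attentive state.** Responses follow a graded response model (GRM) on the
cumulative logits: \(P(y_{j} \ge g \mid \theta) = \mathrm{logit}^{-1}
(\alpha_j \theta + \kappa_{jg})\), with the latent trait standardized to
mean 0, variance 1. Raw responses are modelled; negatively worded items are
not recoded, so their loadings are negative. Because the thresholds enter
with a plus sign, each item's thresholds must be strictly decreasing in
`g`; this is enforced everywhere (containers validate it, estimation
parameterizes thresholds through ordered transforms).

**C/IER state.** Careless responses are assumed content-free: a single
latent *category preference* \(\xi \sim N(0, \sigma^2_\xi)\) with all
loadings fixed to 1 and one shared threshold vector across items. In the
\(\sigma^2_\xi \to 0\) limit the shared thresholds alone determine the
category distribution, which covers purely random responding; larger
\(\sigma^2_\xi\) covers respondent-specific category preferences up to
near-straightlining. The component is deliberately crude — its job is to
absorb many C/IER shapes and deliver a trustworthy occasion-level rate,
not to be interpreted.

Marginal pattern likelihoods integrate the trait out over a 61-node
equally spaced grid on \([-6, 6]\) with normalized normal-density weights
(the category-preference axis is rescaled by \(\sigma_\xi\)). Sixty-one
nodes on that range is the convention of standard marginal-ML IRT engines;
all probability arithmetic is done in log space with log-sum-exp
stabilization.

## Three-step estimation

1. **Mixture fit.** All observations are pooled and treated as independent;
   the observation likelihood is \((1-\pi_2) L_{att}(y) + \pi_2
   L_{cier}(y)\). Estimation is EM: the E-step computes posterior state
   probabilities and expected category counts at the quadrature nodes
   (compiled code); the M-step re-fits each item (and the C/IER component,
   whose \(\sigma_\xi\) acts as a common loading on a standard-normal
   trait) against its expected count table by warm-started quasi-Newton
   steps. EM stops when the largest absolute parameter change falls below
   1e-4 — the convergence flag reported everywhere — or when the
   log-likelihood change falls below 1e-7, whichever comes first, capped
   at 1000 iterations. The log-likelihood trace is recorded and is
   non-decreasing by construction.

   Ten random starts are used (loading magnitudes uniform on 0.5–2.5 with
   signs from the declared item wording, sorted-normal thresholds spanning
   about ±2.5, \(\pi_2 \sim U(0.05, 0.30)\), \(\sigma^2_\xi \sim
   U(0.25, 4)\)). Starts are staged: every start runs a short burn-in
   (default 15 EM iterations), then only starts whose burn-in
   log-likelihood is within 25 of the best (at most 2) continue to full
   convergence. Staging is purely an optimization-schedule choice — the
   start set itself is unchanged — and in our checks the post-burn-in
   ranking selects the same optimum as running every start to convergence,
   at a fraction of the cost. The number of finished starts replicating
   the best log-likelihood (within 0.01) is reported as a multimodality
   diagnostic.

   \(\sigma^2_\xi\) is a free parameter bounded above by 100; estimates at
   the bound are flagged as straightlining-degenerate, since pure
   straightlining drives the category-preference variance toward infinity.

2. **Classification.** Observations are assigned to their modal posterior
   state (ties toward attentive). Because modal assignments are error-prone,
   the classification-error matrix
   \(D[k, l] = \sum_i P(\text{true } k \mid y_i) 1[\text{assigned } l] /
   \sum_i P(\text{true } k \mid y_i)\)
   is computed; it is the fixed measurement model of step 3. `D` is
   computed globally (not per covariate pattern), and zero entries are
   floored at 1e-10 before logs.

3. **Transition model.** A two-state continuous-time latent Markov model is
   fitted to the assignment sequences by maximizing the scaled forward
   likelihood with `D` fixed: initial-state logit (intercept-only by
   default; covariates optional), log-linear transition intensities
   \(\log q_{lk} = \gamma_{0lk} + \gamma_{lk}' z_t\) with covariates taken
   at the destination occasion and intensities held constant within each
   interval, and interval transition matrices
   \(P_\delta = e^{Q\delta}\) computed in closed form for the 2×2 case via
   the stationary decomposition. Optimization starts deterministically at a
   near-identity chain (\(\gamma_0 = \log 0.1\), slopes 0, initial-state
   intercept at the observed first-occasion logit); standard errors come
   from the inverse observed information. Wald tests for a covariate use
   its two transition slopes (df = 2); backward selection removes the
   largest non-significant p-value at \(\alpha = 0.05\) and refits until
   all remaining covariates are significant. Time is measured in hours and
   reported transition probabilities default to a 1-hour interval.

Person-level covariates must be repeated across occasions to enter the
transition model; this inflates the effective sample size, so a warning is
emitted when a covariate is constant within persons.

## The synthetic-data generator

The simulation designs mimic a two-week EMA of a 10-item momentary
satisfaction scale: 75 respondents × 60 occasions, 7-point items, 10% of
observations C/IER, each observation generated independently with its own
trait draw. C/IER patterns: uniform random; strong midpoint preference
(0.80 on the midpoint, 0.05 adjacent, 0.025 elsewhere); straightlining
(one uniformly drawn category copied across all items, redrawn
independently per observation); and the constrained category-preference
GRM with \(\xi \sim N(0,1)\). The mixed-pattern baseline splits C/IER
half-and-half between uniform random and category-preference responding.

Questionnaire manipulations follow the designs exactly: high heterogeneity
multiplies the thresholds of three random items by 0.5 and of three others
by 2.0; wording conditions take absolute loadings and optionally flip two
random items negative; loading decay scales affected items'
loadings by \(d^{(t-1)}\) across occasions (d in 0.99/0.98/0.95 on
2/5/10 items); factor-structure violations draw correlated trait pairs
(rho in 0.80/0.60/0.40) for 20/30/50% of attentive observations with items
1–5 on one factor and 6–10 on the other.

**Surrogate generating parameters.** The validation designs the harness
reproduces were built around empirical parameter estimates that are not
publicly available, so `default_attentive_grm()` and `default_cier_grm()`
are surrogates, flagged as such, calibrated to the documented properties
of that kind of application: a highly reliable, homogeneous satisfaction scale with
two negatively worded items, steep item characteristic curves, strongly
skewed category usage (positive items answered high, negative items
mirrored low), and a C/IER component with category-preference variance
near 1 whose middle categories are nearly dead (responses pile on the two
extreme categories). Concretely the surrogate uses loading magnitudes of
3.5–6 and threshold ranges of about ±7 around a +1 shift on the logit
scale. We verified before freezing the surrogate that milder, symmetric
parameter sets (loadings around 2, thresholds within ±2.5) cannot produce
the separability that validated EMA C/IER detection exhibits — under such
parameters even the Bayes-optimal classifier detects only a quarter of
uniform-random observations — whereas the chosen configuration yields the
characteristic profile: near-0/1 posteriors for random responding, high
precision and specificity, and partial absorption of extreme-category
straightlines by the attentive component in all-positively-worded
questionnaires (negatively worded items make a straight row incoherent
and restore detection). The surrogate reproduces the validation designs
in distribution, not to the third decimal, and all simulation-based
tolerances in the test suite reflect that.

One boundary condition deserves emphasis: for data in which *all* C/IER
is straightlining and no negatively worded items exist, the underestimate
can be far deeper (estimated rates of about 3% against a true 10%) when
estimation stalls — straightlining pushes the category-preference
variance far outside the range that random starting values cover, and
marginal-ML engines started there tend to converge to local maxima with
a shrunken careless component. Our EM with ordered-threshold transforms,
a bounded preference variance and best-of-ten start selection recovers
the straightlining mixture more often, so the underestimate this package
shows in that condition is real but shallower (around 8% instead of 10%).
The straightlining-degenerate flag (`sigma_at_bound`) marks affected
fits.

What the generator deliberately does not emulate: attention-check items,
response times, unplanned missingness patterns, autocorrelated traits
within persons (each observation is generated independently by design),
or person-specific C/IER propensities in the step-1 designs. Passing simulation tests therefore show correct recovery under
the model and its stated violations, not robustness to every feature of
real EMA data.

## Evaluation metrics

`score_replication()` reports the harness's literal definitions:
sensitivity = TP/(TP+FP) (precision of C/IER assignment) and specificity
= TN/(TN+FN), alongside conventional recall and true-negative rate as
secondary columns, plus mean posterior C/IER probabilities in the four
confusion cells. Condition summaries (bias and SD of the estimated rate,
mean sensitivity/specificity) aggregate converged replications only;
convergence is reported as a separate rate. `run_study()` executes the
full Study I/II/III grids with counter-derived per-replication seeds, so
results are independent of execution order.

## Numerical choices and degenerate inputs

* Thresholds are estimated through the transform \(\kappa_1,
  \log(\kappa_{g-1} - \kappa_g)\), keeping orderings strict; gaps are
  bounded in \([e^{-12}, e^{4}]\) and loadings in \([-15, 15]\) for
  numerical safety.
* Category probabilities are floored at 1e-250 inside logs; mixture
  weights at 1e-300.
* Observations with all items missing are dropped (with a warning) before
  fitting; a mixing proportion at the 0/1 boundary produces a warning
  flag, not an error.
* In step 3, a non-finite likelihood at the start triggers a dampened
  restart; a singular observed information produces a pseudo-inverse
  covariance plus a warning flag.
* Ties in modal assignment (posterior exactly 0.5) go to the attentive
  state, documented and tested.
* The 2×2 matrix exponential uses the exact stationary decomposition; any
  alternative must agree to 1e-12 (tested against an eigendecomposition).

## Problem sizes

Full-scale simulation conditions (75×60, 10 starts) are used for the
acceptance script at 10 replications per condition. The test suite runs
the same designs at 4–6 replications per condition, the Wald size study at
200 null datasets of 40×8, and interval-coverage checks at 30 replications
of 120×25 — sizes chosen so the whole suite runs comfortably on a single
desktop core while keeping Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* Estimation supports a unidimensional attentive trait (as in the
  application); multidimensional attentive models exist only on the
  generator side, as violation conditions.
* Step 1 assumes one global mixing proportion over all observations;
  covariates act on transitions (step 3) only.
* The step-2 correction uses a global classification-error matrix;
  per-pattern error matrices are not implemented.
* Persons are not clustered (no mixture latent Markov layer), and
  response-time or attention-check information is not used.
* Detection degrades in the documented boundary conditions: pure
  straightlining without negatively worded items (severe underestimation)
  and strong unmodelled factor-structure heterogeneity (overestimation
  up to ~6 percentage points in the harshest design).
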