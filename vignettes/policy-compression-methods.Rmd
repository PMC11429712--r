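---
title: "Policy compression in 2AFC decisions: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Policy compression in 2AFC decisions: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(policycompress)
```

# The scientific problem

An agent performing a perceptual decision task maps stimuli (states $s$) to
actions $a$ through a policy $\pi(a\mid s)$. Treating the policy as a
communication channel, its *complexity* is the mutual information between
states and actions,

$$I(S;A) \;=\; \sum_s \sum_a P(s)\,\pi(a\mid s)\,
  \log_2 \frac{\pi(a\mid s)}{P(a)} \quad \text{(bits)},$$

and the per-trial *policy cost* is $\log \pi(a\mid s)/P(a)$ — the
information spent conditioning this trial's action on the stimulus. Policy
complexity is exactly the state/action-frequency-weighted average policy
cost. An agent with an information-capacity limit must compress its policy:
keep $I(S;A)$ below capacity while earning as much reward as it can.

This package implements the full analysis pipeline for a two-alternative
forced-choice (2AFC) contrast-discrimination task with 9 signed contrast
states and blockwise 2:1 reward asymmetry: complexity/cost estimation from
choice data, the optimal reward–complexity frontier, maximum-likelihood
fitting of the capacity-limited policy, a cost-penalised actor-critic, and
the regression of outcome-locked dopamine-like responses on outcome, action
value and policy cost. A synthetic-data generator reproduces the task's
statistical structure so every stage is testable without any external
recording.

# The capacity-limited optimal policy

The policy that maximises expected reward at a fixed complexity has the
form

$$\pi(a\mid s) \;\propto\; P(a)\,\exp\{\beta\, Q(s,a)\},$$

where $Q(s,a)$ is the expected reward of action $a$ in state $s$ and the
inverse temperature $\beta \ge 0$ indexes the trade-off: $\beta = 0$
ignores the stimulus entirely (the policy collapses to its own marginal —
perseverative, stochastic responding), $\beta \to \infty$ maximises reward
greedily. Crucially the policy is tilted towards high-marginal-probability
actions, which is what produces bias-shifted psychometric curves in
low-capacity agents.

`blahut_arimoto()` computes this policy at a given $\beta$ by alternating
minimisation: update $\pi(a\mid s) \propto P(a) e^{\beta Q(s,a)}$
row-normalised, then $P(a) = \sum_s P(s)\pi(a\mid s)$, from a uniform
marginal, until the marginal changes by less than `tol = 1e-10` in max
norm (cap `max_iter = 10000`; non-convergence is an error that carries the
last iterate). `frontier()` sweeps a grid of 100 log-spaced $\beta$ values
in $[0.01, 100]$ and prepends the analytic $\beta = 0$ endpoint
$\max_a \sum_s P(s) Q(s,a)$ (zero complexity, the best unconditional
policy). Exponents are stabilised by max-subtraction.

## Units

Costs are reported in nats (natural log), matching the learning rule
below; complexity is reported in bits, the conventional unit for channel
capacity. The conversion $\ln 2$ is applied only at the reporting
boundary, and the identity *mean per-trial cost (nats) $= \ln 2 \times$
plug-in complexity (bits)* holds exactly and is enforced by tests.

## Frontier deviation

Suboptimality of a session with complexity $I$ and average reward $R$ is
measured vertically: $100\,(R_{\mathrm{opt}}(I) - R)/R_{\mathrm{opt}}(I)$,
with $R_{\mathrm{opt}}$ linearly interpolated on the frontier and clamped
at the endpoints. Sessions can land marginally above the frontier
(negative deviation) through estimation noise in the plug-in complexity
and the empirical mean reward; such values are returned as-is rather than
truncated. A horizontal or Euclidean metric would be defensible too; the
vertical gap was chosen because reward is the quantity with natural units
here, and it is what `frontier_deviation()` documents and tests.

# Estimating policies from choices

`estimate_policy()` uses plug-in estimation per session: per-state action
counts with an additive pseudocount $\alpha$ (default 1) so no observed
(state, action) pair ever has probability zero; states never visited get
the uniform row. Sessions have hundreds of trials over 9 states, so the
smoothing bias is small relative to sampling noise. Deliberately no
bias-corrected mutual-information estimators (Miller–Madow, jackknife) are
used — the plug-in estimator keeps the per-trial cost, the complexity and
the regression design internally consistent.

# Fitting the capacity-limited policy

`fit_policy()` treats $\beta$ as the single free parameter. The action
marginal $P(a)$ — the session's bias — is plugged in from empirical choice
frequencies rather than optimised jointly; this matches the estimator the
rest of the pipeline uses for $P(a)$ and keeps the likelihood
one-dimensional. $Q(s,a)$ defaults to the session's empirical mean reward
per (state, action) with never-visited cells filled from the programmed
task rewards, then smoothed across contrast-adjacent states with a
triangular kernel $(w, 1-2w, w)$, $w = 0.25$ by default, renormalised at
the edges — a minimal model of stimulus uncertainty: the animal cannot
perfectly discriminate neighbouring contrasts, so its effective values mix
across neighbours. $w$ must stay below 0.5 or the kernel inverts.

Because $\log \pi(a\mid s;\beta)$ is a concave function of $\beta$
(log-sum-exp), the summed log-likelihood is concave, and a single bounded
golden-section search on $\beta \in [0, 50]$ (`stats::optimize`) finds the
global maximum; no multistart is needed. The boundary $\beta = 0$ is
checked explicitly because the optimum can sit on it for uninformative
choices. BIC uses $k \ln n - 2\,\ell$ with $k = 2$ for the with-bias model
(the plug-in bias is counted as an estimated parameter) and $k = 1$ for
the bias-free variant; `compare_bias_models()` reports
$\Delta\mathrm{BIC} = \mathrm{BIC}_{\text{no bias}} -
\mathrm{BIC}_{\text{bias}}$ both summed over per-session fits and for a
single pooled fit, since either aggregation is defensible.

# The cost-penalised actor-critic

The learning model couples a critic $V(s)$, an actor with preferences
$\theta(s,a)$ and a running estimate $\hat P(a)$ of the agent's own action
marginal. The policy is $\pi(a\mid s) \propto
\exp\{\theta(s,a) + \log \hat P(a)\}$ and the teaching signal is

$$\delta \;=\; r - V(s) - \tfrac{1}{\beta}\,
  \log\frac{\pi(a\mid s)}{\hat P(a)},$$

i.e. the reward prediction error penalised by the policy cost. With
$\beta = 1$ the penalty enters with unit weight; the $1/\beta$ scaling is
used so that the algorithm's fixed point is exactly the capacity-limited
optimal policy at that $\beta$: setting the expected update of
$\theta(s,\cdot)$ to zero forces $\bar r(s,a) - \frac1\beta \log
\frac{\pi(a|s)}{P(a)}$ to be constant in $a$, i.e. $\pi(a\mid s) \propto
P(a)e^{\beta Q(s,a)}$. Updates are the standard delta rule for $V$, the
likelihood-gradient (softmax actor) step
$\theta(s,a') \mathrel{+}= \alpha_\theta\,\delta\,(\mathbf 1[a'=a] -
\pi(a'\mid s))$, and an exponential tracker for $\hat P(a)$.

## Why the learning rates look the way they do

Two numerical facts shaped the defaults, both visible in simulation:

* With constant step sizes a stochastic-approximation scheme does not
  converge — it orbits its fixed point at a radius set by the step size.
  At $\alpha_\theta = 0.1$ the orbit is wide enough to exceed a
  total-variation gap of 0.2 from the optimum at low $\beta$.
  `run_agent()` therefore anneals the critic and actor on a
  Robbins–Monro-style schedule $\alpha_t = \alpha\,\tau/(\tau + t)$ with
  $\tau = 5000$ trials, and reports as "terminal policy" the average of
  $\pi$ over the final 40% of trials.
* On a symmetric task the action marginal is a nearly *neutral* direction
  of the coupled dynamics: if $\hat P(a)$ drifts, the policy tilts with
  it, the tilted policy emits tilted actions, and the tracker sees its own
  drift reflected back — the restoring gain is only a few percent per
  update (the same degeneracy that underlies matching behaviour). The
  equilibrium drift scales as $\sqrt{\alpha_m}$, and
  $\alpha_m = 10^{-4}$ keeps it near 0.01 over a 50,000-trial run, which
  is why the marginal tracker is so much slower than the actor
  ($\alpha_v = \alpha_\theta = 0.1$).

With these defaults the terminal policy matches the Blahut–Arimoto optimum
within total variation 0.05 per state at $\beta \in \{0.5, 2, 5\}$ over
50,000 trials, and its (complexity, reward) point sits on the frontier
within a fraction of a percent. The fixed point, not the trajectory, is
the scientific claim; no attempt is made to model the animals' learning
curves.

# The synthetic study

`generate_dataset()` emulates the structure of a 55-session photometry
experiment. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| contrasts | $0, \pm 6.25, \pm 12.5, \pm 25, \pm 50\%$ | 9 symmetric levels, standard for this task family |
| state distribution | uniform (1/9) | configurable, since $P(s)$ enters the frontier |
| block length | 100 trials | alternating `left_large` / `right_large` blocks, first type random |
| reward asymmetry | 2 : 1 | the large side pays exactly double |
| sessions × trials | 55 × 400 | matches the scale of the emulated experiment |
| $\beta$ range | $U[0.5, 5]$ | spans perseverative to near-greedy behaviour |
| bias range | $U[0.3, 0.8]$ | session-level marginal $P(\text{right})$ |
| response noise | $\sigma = 0.5$ | Gaussian, on the windowed scalar |

Choices are sampled from the capacity-limited policy evaluated at the
task's block-averaged $Q$ — the policy conditions on the 9 stimulus states
only, not on the block, so a session's (complexity, reward) point lies on
or below the 9-state frontier up to sampling noise. (A block-conditioned
policy would exploit information outside the frontier's state space and
sit systematically above it.) Zero-contrast trials are rewarded on a
uniformly random side, so either action earns half its magnitude in
expectation.

Outcome responses follow the generative model
$\text{response} = g\, r - V(s) - \text{cost} + \varepsilon$, with $V$ and
cost evaluated under the generating policy, $\varepsilon \sim N(0,
\sigma^2)$, and a session gain $g$. By default $g$ scales with the
session's $\beta$ (normalised to mean 1 across the $\beta$ range),
emulating inverse-temperature-controlled reward sensitivity — the
mechanism that makes the per-session outcome coefficient correlate with
the behaviourally fitted $\beta$. Optionally each response is embedded as
a boxcar in the 300–800 ms window of a flat trace so the windowing step
can be exercised end-to-end.

What the generator does *not* emulate: sensory noise in the stimulus
representation beyond value smoothing, within-session learning or block
adaptation, trial history effects, calcium-indicator dynamics (the trace
is an idealised boxcar), photometry artefacts, and across-animal
structure. Tests passing on this generator therefore certify the
*estimators and algorithms* — not that real dopamine responses follow the
generative model.

# The outcome-response regression

`window_response()` averages the trace over 300–800 ms after outcome
delivery and subtracts the mean over a 200 ms baseline centred on the
outcome, interpreted as $[-100, 100)$ ms with half-open sample intervals.
Responses are z-scored within session (`zscore_within_session()`, exact
zero-variance sessions are an error) and pooled into one ordinary
least-squares regression on intercept, policy cost (nats, from the
session's plug-in policy), action value ($Q$ at the chosen action, from
the smoothed empirical table) and outcome (delivered water amount). No
random effects are used — within-session standardisation is the
aggregation device. BIC is Gaussian with the variance profiled out,
$n \ln(\mathrm{RSS}/n) + k \ln n$, and
`compare_cost_models()` reports the penalty for dropping the cost column.
`partial_residuals()` adds a regressor's fitted contribution back to the
residuals; regressing that on the regressor alone returns the multiple-
regression coefficient exactly (Frisch–Waugh), which the tests enforce at
$10^{-8}$. The $\beta$–outcome-coefficient association
(`correlate_beta_outcome()`) uses Pearson correlation with a two-sided
$t$-based p-value.

# Degenerate inputs and tie-breaking

* All-one-action sessions: the empirical bias is clipped to
  $[\tfrac{1}{2n}, 1-\tfrac{1}{2n}]$ with a warning.
* $P(a\mid s) = 0$ for an observed pair is an error in `policy_cost()` —
  it cannot occur with pseudocount smoothing.
* Argmax ties in deterministic-limit checks resolve to the lowest-index
  action; the zero-contrast state carries equal values by construction.
* `smooth_values()` rejects $w \ge 0.5$; edge states renormalise over the
  available neighbours, so constant value tables are exactly invariant.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at these scales, chosen as the package's standard verification
conditions: 1,000 (MI oracle) and 10,000 (frontier dominance) random
policies; 50 sessions × 500 trials for inverse-temperature recovery; 20
sessions × 500 trials per arm of the bias model comparison; 50,000 agent
trials per $\beta$; and 20 replicate datasets of 55 sessions × 400 trials
for the regression sign-pattern check.

# Known limitations

* Plug-in complexity is biased upward at session sizes of a few hundred
  trials; the frontier-deviation distribution inherits that bias. This is
  deliberate (it matches the estimator used throughout), but absolute
  deviations should be read with it in mind.
* The BIC parameter counts ($k = 2$ vs $1$; regression $k$ = number of
  columns) are conventions; both are documented and configurable where
  they matter.
* Per-session fits are independent — no hierarchical pooling across
  sessions or animals.
* The actor-critic is a single-step task model: no eligibility traces,
  discounting, or meta-learning of $\beta$.
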