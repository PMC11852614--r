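---
title: "A Bayesian choice-consistency model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian choice-consistency model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choicesym)
```

## The model

`choicesym` simulates an agent that repeatedly observes a scalar stimulus,
chooses one of a small set of discrete actions, receives a scalar reward,
and then re-estimates the parameters of its own choice policy so as to
balance two pressures: earning reward, and being *consistent with its own
recent choices*. The second pressure is the interesting one — it alone is
enough to break the symmetry of an initially indifferent agent and commit
it, irreversibly and idiosyncratically, to a particular mapping from
stimuli to actions.

Three probability models define one step at time $k$:

* **Stimulus.** $s_k \sim \mathcal N(0, \sigma_s^2)$.
* **Action.** Actions live at the integer locations $1, \dots, N_a$. A
  mixture of $N_w$ Gaussian bumps with common width $\sigma_a$ is placed on
  the action axis; the $i$-th bump has mean $w_i^0 + w_i^1 s_k$, an affine
  function of the stimulus. The probability of action $a$ is the mixture
  density evaluated at $a$, renormalized over the $N_a$ action locations.
  The weight vector $w = (w_1^0, w_1^1, \dots, w_{N_w}^0, w_{N_w}^1)$ holds
  the agent's learnable parameters.
* **Reward.** $r_k \sim \mathcal N(\mu(a_k, s_k), \sigma_r^2)$ with
  $\mu(a, s) = \alpha\,(a - \beta)\,s$. With the standard
  $\alpha = 2, \beta = 3/2$ this pays action 1 for negative stimuli and
  action 2 for positive ones, symmetrically; an additive variant
  $\mu = \alpha a + \beta s$ is available as a configuration switch but is
  not the default, because it cannot express the intended
  stimulus-contingent reward design.

The agent keeps a bounded FIFO memory of the last $\Delta$ triples
$(s_j, a_j, r_j)$. Once the memory is full, every step re-estimates $w$ by
minimizing the **compromise loss**

$$\ell_\lambda(w) \;=\; \lambda\, \ell_r(w) \;+\; (1 - \lambda)\,\ell_a(w),
\qquad 0 \le \lambda \le 1,$$

where

* $\ell_a(w) = -\sum_j \log p(a_j \mid s_j, w)$ is the *consistency loss*:
  the summed surprisal of the remembered actions under the candidate
  policy. The sum (not the mean) is used, so the loss visibly climbs while
  the memory fills and collapses when the policy locks onto a consistent
  map — the signature of the symmetry-breaking transition.
* $\ell_r(w) = -\frac1\Delta \sum_j \sum_a p(a \mid s_j, w)\,\mu(a, s_j)$
  is the *reward loss*: the negative expected mean reward of the candidate
  policy over the remembered stimuli. It is computed analytically from the
  Normal reward model (a configuration switch substitutes the recorded
  rewards); it is averaged rather than summed so that the two terms have
  comparable magnitude when $\lambda$ mixes them.

At $\lambda = 0$ (the standard setting) only choice consistency drives
learning; at $\lambda = 1$ only reward does.

## The per-step update

Minimization uses the Nelder–Mead simplex search in the Lagarias et al.
formulation (reflection 1, expansion 2, contraction 0.5, shrink 0.5;
termination when both the simplex function spread and vertex spread fall
below their tolerances, default $10^{-6}$; iteration cap $200 \cdot
\dim(w)$). It is implemented in compiled code because it runs once per
simulation step — hundreds of thousands of times in a batch experiment.

Three numerical decisions matter far beyond their apparent size. They are
worth stating bluntly, because the qualitative behavior of the model
depends on them.

**The underflow boundary is the determinism cap.** The pmf is the naive
renormalized density: a sum of Gaussian ordinates divided by their total.
When every action's density underflows (all component means further than
about $38.6\,\sigma_a$ from the whole action grid at some remembered
stimulus), the loss evaluation reports a *policy collapse* sentinel — the
largest representable loss — and the simplex retreats. Because the
surprisal of a perfectly fitted window keeps strictly decreasing as the
weights grow, a converging optimizer would otherwise push the slope weight
to machine-underflow saturation (values in the thousands), making the
policy exactly deterministic and freezing the stimulus–action boundary
forever. The collapse sentinel caps the weights at the underflow boundary
instead, keeping a sliver of stochasticity alive near the decision
boundary; that residual noise is what lets the boundary keep drifting and
ultimately lets one action take over. The cap is not a tuning knob — it is
where IEEE double precision puts it.

**Sampling uses the degenerate-policy limit.** The optimizer pins weights
*near* the underflow boundary of the remembered stimuli, so a fresh
stimulus slightly more extreme than any remembered one can underflow the
naive pmf. The simulator therefore samples from the well-defined limit of
the renormalized mixture (computed in log space): a point mass on the
action nearest the closest component mean. The exported `action_pmf()`
signals `policy_collapse` by default and exposes the limit via
`limit = TRUE`.

**Re-estimation restarts from the initial weights.** Each step's simplex
search starts from the run's initial weight vector rather than from the
previous estimate (`update_start = "initial"`, with `"previous"`
available). The reason is the flat basin past separability: when the
memory window is linearly separable, the set of minimizing weight vectors
is a plateau at (numerically) zero loss, and a warm-started simplex simply
stays put — in experiments with warm starts, three quarters of standard
runs never lost an action. Restarting makes the fitted boundary track the
sliding memory window, which reproduces the continuous drift of the choice
regions and the universal eventual takeover that the model is built to
study.

One further optimizer detail: the initial simplex perturbs nonzero
coordinates by 5% and zero coordinates by an absolute `zero_delta = 0.05`.
The conventional near-degenerate zero perturbation (0.00025) elongates the
simplex along the intercepts and can permanently stall the slope
direction; at $\lambda = 1$ that pathology trapped a large fraction of
runs in "always one action" solutions, violating the exact limit in which
pure reward weighting never extinguishes an action. With `zero_delta =
0.05` the limit holds exactly. The trade-off is documented under
*Limitations*.

## Standard parameters

The defaults of `sim_config()` are the study conditions: initial weights
$(1.5, 0)$ — a single component whose mean sits exactly midway between the
two actions, so the initial choice is a coin flip at every stimulus —
$N_a = 2$, $\Delta = 20$, $\lambda = 0$, $\sigma_a = \sigma_r = 1$,
$(\alpha, \beta) = (2, 3/2)$, and 600 steps. $\sigma_s$ is not part of the
published standard set; it defaults to 1, matching every other dispersion
parameter, and at $\lambda = 0$ the dynamics are invariant to it (only the
ratio of stimulus spread to the action-grid spacing enters, through the
underflow cap). Longer conditions (memory 40; three or more actions) run
1500 steps so that stoppage times have headroom of roughly the mean plus
three standard deviations.

## Measuring the outcomes

`stoppage_times()` reports, per action, the last step at which it was
sampled; actions still being sampled in the final $\Delta$ steps are
censored (winners). A losing action's stoppage time is its
last-occurrence index. Runs in which no action stops within the horizon
are excluded from stoppage means and counted separately.

`classify_run()` assigns one behavior label per run. Sliding windows (100
steps, stride 10) cover the post-warmup record up to the earliest losing
stoppage. Within a window, each action's stimuli are split into occupied
*bands* (gaps larger than 4 times the median within-band spacing split a
band), and two actions count as separated when fewer than 15% of either's
stimuli fall inside the other's bands. The window-level measure is
band-based rather than span-based deliberately: a sandwich geometry — one
action's band nested between two bands of the other — is separation in
every meaningful sense, yet the inner band always lies inside the outer
action's overall span. A window is *sandwich-patterned* when band owners
interleave along the stimulus axis and the pattern holds in both halves of
the window (a drifting threshold boundary, aggregated over 100 steps, can
mimic interleaved bands; a genuine sandwich map survives the split-half
check). The run labels, in precedence order:

* `non_discriminating` — one action exceeds 95% of samples in every
  post-warmup block, with no discriminated window anywhere;
* `sandwich` — at least two sandwich-patterned windows;
* `switching` — discriminated windows occur with both dominance
  directions (judged by the median stimulus per action, from non-sandwich
  windows);
* `full_discrimination` — at least two discriminated windows with a
  consistent direction;
* `intermingled` — everything else: no discrimination phase forms before
  one action takes over.

The classification is judged on the *pre-takeover* record on purpose:
during the final takeover the winning action invades the loser's stimulus
band, so the last 100 steps of almost every run look intermingled
regardless of how cleanly the run discriminated beforehand. All thresholds
are exposed in `classifier_options()`.

`dominance_direction()` reports which action ends up eliciting the larger
stimuli (the direction of the last discriminated window, with a
median-comparison fallback), `stoppage_regression()` fits second-vs-first
losing stoppage times across multi-action runs, `batch_run()` aggregates
forty-run batches with binomial standard errors, and `lambda_sweep()`
tabulates dominance and stoppage against $\lambda$.

## What the synthetic trajectory bank shows — and what it does not

The classifier's accuracy test uses trajectories generated from *known
stationary rules* (threshold maps, sandwich maps, independent labels,
dominant-action rules, mid-run direction flips) plus a small label noise.
Against that bank the classifier is required to agree with the generating
rule at least 95% of the time. Passing this says the operationalization is
faithful to the taxonomy's definitions; it does not certify agreement with
by-eye classification of real simulation output, whose boundaries drift
continuously and whose class frequencies therefore depend on how much
within-window drift the separation criterion tolerates.

## Problem sizes

Batch statistics in the tests and the acceptance script use forty runs per
condition — the scale at which the original statistics are quoted, and the
scale at which their standard errors are meaningful. Single-run contract
tests use 60–400 steps. A standard 600-step run takes well under a second;
a forty-run batch of 1500-step simulations takes about a minute on one
core.

## Known limitations

* **Timescale.** The reconstructed dynamics break symmetry and extinguish
  losing actions more slowly than the published statistics by a factor of
  roughly 1.4–2 depending on condition (for example, mean losing-action
  stoppage near 220 steps at memory 20 against a published 160). The
  drift speed is governed by the per-step re-estimation noise near the
  underflow-capped policy — a quantity sensitive to optimizer details
  (starting point, simplex construction, stopping behavior) that the
  model statement leaves open. The structural statistics are much less
  sensitive: the second-vs-first stoppage correlation, its unit
  slope, the roughly 20-iteration separation between successive
  extinctions, and the direction of the memory-length effect all
  reproduce.
* **Multi-action segmentation rates.** With three or more actions (and
  with four choice parameters) the discrimination-class percentages come
  out lower than published. The step-to-step jitter of the fresh-start
  re-estimation smears the per-window stimulus bands that the overlap
  criterion tests; smoother boundary motion would classify higher.
* **`zero_delta` trade-off.** The 0.05 zero-coordinate perturbation is
  required for the exact $\lambda = 1$ limit (no stoppage, fully
  reward-aligned dominance) and for sandwich behavior to appear at all,
  but it slows three-action extinction times relative to the
  near-degenerate 0.00025 setting, under which those times match the
  published values more closely while the $\lambda = 1$ limit fails. Both
  regimes are one `optimizer_options(zero_delta = )` call away.
* The interior $\lambda$ behavior (between the exact limits) mixes a
  log-scale consistency term with a linear-scale reward term; the sweep's
  sigmoid transition location depends on that scaling convention.

## A worked single run

```{r single-run}
traj <- run_simulation(sim_config(seed = 1))
run_summary(traj)$behavior
stoppage_times(traj)
```

```{r loss-trace, fig.width = 6, fig.height = 3}
plot(traj$t, traj$loss_a, type = "l", xlab = "step",
     ylab = "consistency loss",
     main = "climb while memory fills, collapse at the transition")
```
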