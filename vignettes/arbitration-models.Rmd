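---
title: "Dual-system reinforcement learning with dynamic arbitration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-system reinforcement learning with dynamic arbitration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arbRL)
```

## The problem

In probabilistic reversal learning, a subject repeatedly chooses between two
options whose reward probabilities (80/20, 70/30 or 60/40) reverse once,
unannounced, partway through each block of 80 trials. When reward can attach
either to *stimulus identity* ("What" blocks) or to *response side* ("Where"
blocks), the learner faces a credit-assignment problem on top of the usual
reward uncertainty: which dimension of its own choice should feedback be
assigned to? `arbRL` implements a family of reinforcement-learning models of
this behavior in which two value-learning systems — one over stimuli, one
over actions — run in parallel and compete for control of choice, together
with the simulation, fitting and analysis machinery around them.

## The model family

Every model shares the same per-trial value dynamics. The chosen option's
value moves toward the obtained reward $R(t)\in\{0,1\}$ with a learning rate
that differs for rewarded and unrewarded trials,
$$V_C(t+1) = V_C(t) + \alpha_{+}\,(R(t)-V_C(t)) \quad\text{or}\quad
  V_C(t+1) = V_C(t) + \alpha_{-}\,(R(t)-V_C(t)),$$
while the unchosen option's value passively decays toward zero,
$V_U(t+1) = (1-\zeta)V_U(t)$. The probability of a rightward choice is a
softmax in the overall values of the two sides,
$$P_\mathrm{Right} = \mathrm{logistic}\bigl(\beta_1(OV_\mathrm{Right}
  - OV_\mathrm{Left}) + \beta_0\bigr),$$
with inverse temperature $\beta_1$ and side bias $\beta_0$.

The models differ in how the overall values are formed:

* **`stim_only` / `action_only`** — a single system supplies the values
  (stimulus values mapped to sides through the trial's stimulus placement,
  or action values directly).
* **`static_omega`** — both systems run in parallel and are mixed with a
  fixed weight: $OV_i = \omega V_{\mathrm{Stim}(i)} + (1-\omega)V_{\mathrm{Action}(i)}$.
* **`dynamic_omega_*`** — the weight $\omega(t)$ is re-arbitrated every
  trial from the *relative reliability* $\Delta\mathrm{Rel}$ of the two
  systems. Four reliability signals are implemented: the signed difference
  of the chosen option's values in the two systems (`vcho`), the difference
  of unsigned prediction-error magnitudes (`absrpe`), value discernibility
  $|\Delta V|$ (`absdv`), and summed signal strength $\Sigma V$ (`sumv`).
  Positive signals drive $\omega$ toward 1 at rate
  $\alpha_\omega\Delta\mathrm{Rel}$, negative ones toward 0, and a passive
  decay $\zeta_\omega$ always pulls $\omega$ back to its block-initial value
  $\omega_0$.
* **`dynamic_omega_rho`** — additionally separates *baseline* signal
  strength from *dynamic* arbitration:
  $OV_i = \rho\,\omega(t)V_{\mathrm{Stim}(i)} + (1-\rho)(1-\omega(t))V_{\mathrm{Action}(i)}$,
  with $\rho$ a per-subject constant. The net weighting of the stimulus
  system is summarized by the effective weight
  $\Omega = \rho\omega / (\rho\omega + (1-\rho)(1-\omega))$, which reduces
  to $\omega$ at $\rho = 0.5$.

The reliability signal indexes the trial's own values — the state the choice
was made with, before the value update. Under this convention the signed
chosen-value difference equals the difference of the two systems' prediction
errors, $\Delta V_\mathrm{cho}(t) = \mathrm{RPE}_\mathrm{Action}(t) -
\mathrm{RPE}_\mathrm{Stim}(t)$, on every trial; the test suite asserts this
identity to machine precision. (Evaluating the signal on post-update values
would shrink it by $1-\alpha$ and break that identity; it also fails to
reproduce the arbitration regimes described below.)

### Parameters, bounds and defaults

| parameter | meaning | bounds |
|---|---|---|
| $\alpha_+,\alpha_-$ | learning rates (rewarded / unrewarded) | $[0,1]$ |
| $\zeta$ | decay of the unchosen value | $[0,1]$ |
| $\beta_1$ | inverse temperature | $[0,100]$ |
| $\beta_0$ | side bias (positive = rightward) | $[-5,5]$ |
| $\omega$, $\omega_0$ | (initial) arbitration weight | $[0,1]$ |
| $\alpha_\omega$ | arbitration rate | $[0,1]$ |
| $\zeta_\omega$ | arbitration decay toward $\omega_0$ | $[0,1]$ |
| $\rho$ | baseline stimulus/action signal ratio | $[0,1]$ |

The box above is the fitting default (`rl_bounds()`); it can be overridden
per fit. Free-parameter counts entering the AIC follow directly from the
model definitions (5 for the single-system models, 6 for `static_omega`, 8
for the dynamic models, 9 for `dynamic_omega_rho`; a parameter pinned via
`fixed=` is not counted).

### Numerical choices

* **Value initialization.** All four values start at `v_init = 0.5`, the
  midpoint of the reward range, so the initial reliability difference is
  zero and arbitration starts unbiased; `v_init = 0` is available. The
  state (both systems and $\omega$) resets at every block boundary, since
  each block introduces novel stimuli; a `carry_action` flag optionally
  carries action values across blocks within a session (response sides, unlike
  stimuli, persist).
* **Likelihood floor.** Per-trial probabilities are clipped to
  $[10^{-10}, 1-10^{-10}]$; likelihoods are in natural log, entropies in
  bits.
* **Boundedness of $\omega$.** The drive-plus-decay update can leave
  $[0,1]$ in an extreme corner of the parameter box (only when
  $\alpha_\omega + \zeta_\omega > 1$), and the `sumv` reliability signal
  ranges over $[-2,2]$ rather than $[-1,1]$. Two guards make the update
  closed over the whole box: the effective step $\alpha_\omega|\Delta
  \mathrm{Rel}|$ is capped at 1, and the result is clipped to $[0,1]$.
  Both are inactive in the usual operating regime.
* **Degenerate corner of $\Omega$.** Where the denominator of the effective
  weight vanishes ($\rho$ and $\omega$ at opposite corners), $\Omega$ is
  defined as $\omega$ by continuity along $\rho = 0.5$.
* **Optimization.** `fit_rl()` minimizes the session negative log-likelihood
  with bounded L-BFGS-B from uniform-random interior starts plus the box
  midpoint; the per-trial loop is compiled (Rcpp), and a pure-R reference
  engine built from the exported primitive operations is cross-checked
  against it in the tests. 20 starts is the desk-scale default; 100
  reproduces the full protocol. Ties in AIC selection break toward fewer
  parameters.

## Strategy metrics

The *entropy of reward-dependent strategy* (ERDS) is the conditional
Shannon entropy, in bits, of staying vs. switching given the previous
trial's outcome, computed separately on the stimulus dimension (did the
subject re-choose the same image?) and the action dimension (the same
side?). A perfectly outcome-driven rule (e.g. win-stay/lose-switch) scores
0; outcome-blind coin-flipping scores 1. Probabilities are empirical
plug-in frequencies with $0\log 0 := 0$ and no smoothing; windows
containing only wins (or only losses) score the entropy of the single
observed branch. `sliding_dominance()` labels trials stimulus- or
action-dominant by comparing the two ERDS values over a trailing 10-trial
window that never crosses block boundaries; trailing (causal) windows are
used so labels could be aligned with concurrent behavior downstream, and
exact ties are flagged for exclusion. The window convention is switchable
via the `window` argument.

## Arbitration-rate analysis

From a per-trial $\Omega$ trajectory, `effective_rates()` decomposes each
step into normalized rates toward the stimulus system,
$\psi_+ = [\Delta\Omega]^+ / (1-\Omega)$, and toward the action system,
$\psi_- = [\Delta\Omega]^- / (0-\Omega)$ — the arbitration analogue of a
learning rate. At $\Omega \in \{0, 1\}$ the rate without headroom is
defined as 0. The decomposition inverts exactly: reconstructing the
trajectory from the rates is the identity. `delta_psi_post_reversal()`
summarizes a block by $\Delta\psi = \bar\psi_+ - \bar\psi_-$ over the
trials at and after the reversal, where the initial-bias transient has
passed.

`align_and_smooth()` places blocks with random reversal positions on a
common 60-trial axis (20 trials forward from block start, 20 forward from
the reversal, 20 backward from the block end — the forward/backward reading
of "relative to beginning, reversal and end" keeps every segment inside its
phase), averages across blocks, and smooths with a centered 5-trial moving
window applied strictly within segments, so acquisition-phase bins never
mix with post-reversal values. Blocks too short around an anchor contribute
masked entries. Group contrasts on subject-level summaries use a two-sided
permutation test (10,000 shuffles by default) whose p-value counts the
observed labeling in both numerator and denominator, so it is never zero.

## The synthetic-data generator

`make_block_spec()` reproduces the task structure: 80-trial blocks, the
reward schedule drawn uniformly from \{80/20, 70/30, 60/40\}, a single
unsignaled reversal drawn uniformly from trials 30–50 inclusive (21
values), What/Where block types equiprobable in the two-dimensional task,
and the initially better target drawn uniformly. Stimulus sides are
assigned i.i.d. with probability 0.5 per trial; an exact within-block
counterbalance is available (`balance_sides = TRUE`) since the original
task's counterbalancing scheme is not specified. Sessions default to 20
blocks, the task's typical session length. Aborted or repeated trials are
not modeled, and the deterministic 100/0 schedule exists only as a
degenerate test case. Simulation is a pure function of
`(model, params, blocks, seed)`; cohorts derive per-(subject, session)
sub-seeds deterministically so they are reproducible piecewise.

`generate_cohort()` emulates the three experimental groups through the
`dynamic_omega_rho` parameters that distinguish them: controls
($\omega_0 = 0.374$, $\rho = 0.6$ — fitted control baseline ratios sit
above one half, e.g. 0.61 in the worked example block), an
amygdala-lesion-like group with a reduced initial arbitration weight
($\omega_0 = 0.179$, $\rho$ unreduced), and a ventral-striatum-lesion-like
group with a reduced baseline ratio ($\rho = 0.4$, $\omega_0 = 0.276$).
Remaining parameters default to the reference values used across the
simulation experiments ($\alpha_\pm = 0.5$, $\zeta = 0.3$, $\beta_1 = 20$,
$\beta_0 = 0$, $\alpha_\omega = 0.2$, $\zeta_\omega = 0.05$), with modest
truncated-normal subject-level spread, and $\rho$ is constant across a
subject's sessions.

What the generator does *not* emulate: reaction times, aborted fixations,
session-level drifts (fatigue, long-term compensation), perseverative
kernels beyond the side bias, and any across-block carry-over of stimulus
knowledge. Tests that pass on this generator therefore certify the
machinery — estimator consistency, selection behavior, metric algebra —
under the model's own assumptions, not the adequacy of those assumptions
for any particular real dataset.

## Simulation experiments and their design choices

* **Parameter recovery** (`parameter_recovery()`) samples generating
  parameters per session from plausible ranges (e.g. $\beta_1 \in [5,30]$,
  $\omega_0 \in [0.1, 0.7]$ — very low inverse temperatures yield
  pure-noise sessions that no method can recover), simulates fresh
  environments, and refits. For `dynamic_omega_rho` the baseline ratio is
  treated exactly as in fitting real subjects: $\rho$ is a per-subject
  constant, recovered by a stage-1 joint fit of all the subject's sessions
  and then fixed for stage-2 per-session fits. Freeing $\rho$ per session
  instead leaves a $(\beta_1, \rho, \omega_0)$ trade-off that visibly
  degrades recovery of $\beta_1$ and $\omega_0$ — one motivation for the
  two-stage procedure.
* **Model recovery** (`model_recovery()`) draws generating parameters
  uniformly over the documented bounds, except $\beta_1 \sim U(1, 40)$:
  uniform over $[0,100]$ would place mass both on unidentifiable
  near-zero temperatures and on implausibly deterministic ones never seen
  in fits of this task family. Sessions are 30 blocks; selection is by
  AIC.
* **The lesion grid** (`lesion_grid_sim()`) crosses $\omega_0$, $\rho$ and
  $\beta_1$ with all other parameters at the reference values, on What
  blocks with the reversal fixed at trial 40, and reports per-cell
  $\Delta\psi$, mean $\omega$/$\Omega$ trajectories and P(Better). The
  control/amygdala cells are evaluated at $\rho = 0.6$ (the control-like
  baseline ratio; at $\rho = 0.5$ the control cell's per-block $\Delta\psi$
  sits at zero rather than clearly positive) and the VS cells at
  $\rho = 0.4$. The long single-reversal stimulus-learning variant is the
  same function with `n_trials = 200, reversal = 100`.
* **ERDS interaction** (`erds_interaction_sim()`) simulates What-only
  cohorts from single- and two-system generators on matched seeds and
  regresses per-block ERDS on the action dimension on the
  subject-mean-centered stimulus-dimension ERDS with per-subject
  intercepts — a transparent fixed-effects stand-in for a random-intercept
  model with the same point estimate in this balanced design. Two-system
  generators produce more negative slopes (competition); the single-system
  generator's slope is near zero.

Desk-scale problem sizes are used throughout the test suite and the
acceptance script — 30 sessions of 20 blocks for parameter recovery, 200
sessions for model recovery, 5-fold cross-validation with 10 repeats, 2,000
blocks per grid cell — and the full-protocol sizes (100 optimizer starts,
50 cross-validation repeats, 10,000 blocks per cell) are plain argument
changes.

## Known limitations

* $\alpha_\omega$ and $\zeta_\omega$ recover weakly at 20 blocks per
  session; they shape trajectories more than likelihoods at this data
  volume. The criteria the package tracks ($\beta_1$, $\alpha_+$,
  $\omega_0$, subject-level $\rho$) recover well.
* In the saturated-softmax regime (large $\beta_1$) learning rates are
  poorly identified — the likelihood is flat in $\alpha_+$ once value
  differences exceed the sigmoid's dynamic range. The recovery experiments
  avoid that regime by design.
* Hierarchical (multi-level) estimation, reaction-time modeling and
  mixed-effects inference on group contrasts are out of scope; the
  permutation test covers the small-sample group comparison the package
  needs.

## A worked example

```{r, eval = FALSE}
library(arbRL)
cohort <- generate_cohort(cohort_spec("control", n_subjects = 2,
                                      n_sessions = 2), seed = 1)
one_session <- subset(cohort$trials, subject == "co01" & session == 1)
fit <- fit_rl(one_session, "dynamic_omega_rho", n_starts = 20, seed = 1)
print(fit)
plot(fit)                      # aligned mean effective-weight trajectory
erds_by_block(one_session)     # per-block strategy metrics
```
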