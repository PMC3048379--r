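---
title: "Setpoint state-space models of strategy use during visuomotor adaptation"
author: "setpointadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Setpoint state-space models of strategy use during visuomotor adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setpointadapt)
```

## The model family

Trial-by-trial adaptation to a visuomotor rotation is classically
described by a state-space model: the motor system keeps an estimate
$\hat{x}_n$ of the rotation $r_n$ and updates it from the error it
observes,

$$e_n = r_n - \hat{x}_n, \qquad \hat{x}_{n+1} = A\,\hat{x}_n + B\,e_n,$$

with retention $A$ and adaptation rate $B$ (both dimensionless, in
$[0,1]$; angles are degrees, clockwise positive, counter-clockwise
negative). This model compensates gradually and cannot express what
happens when a participant is *instructed* to aim $s^\* = 45^\circ$
clockwise to offset a $-45^\circ$ rotation: compensation is then
immediate.

The setpoint family adds a strategy state $s_n$ with **direct
feedthrough** to the output: the hand goes where the strategy says, so
the target error becomes $e_n = r_n - \hat{x}_n + s_n$, zero on the very
first strategy trial. The critical assumption is that implicit adaptation
is driven not by the target error but by the **aiming error** — the
discrepancy between the feedback cursor and the *aiming location*, the
setpoint around which the internal model recalibrates. Re-aiming moves
the setpoint with it, so the aiming location is the current strategy
state, weighted by its availability $K$:

$$\hat{e}_n = r_n - \hat{x}_n + (1 - K)\,s_n, \qquad
  \hat{x}_{n+1} = A\,\hat{x}_n + B\,\hat{e}_n .$$

With a fixed strategy ($s_n = s^\*$) and $K = 1$ the strategy cancels out
of the error entirely, $\hat{e}_n = r_n - \hat{x}_n$: the internal model
keeps adapting although performance is perfect, and the target error
*drifts* toward $s^\*$ — reaching it exactly, in the limit, when $A = 1$.
$K < 1$ (aiming landmarks briefly visible, or absent) attenuates the
asymptotic drift to $K \cdot s^\*$; `fixed_point()` returns these
equilibria in closed form.

Finally, participants do not tolerate unbounded error: the full dynamic
variant lets the strategy be re-adjusted by the target error,

$$s_{n+1} = E\,s_n - F\,e_n,$$

with strategy retention $E$ and adjustment rate $F$. Drift then rises and
is eventually offset by re-aiming; the system approaches a
pseudo-equilibrium where aiming error and target error balance. Because
the internal model keeps adapting while the strategy corrects
performance, the model predicts that the **aftereffect** (residual error
when rotation, strategy and feedback are all removed, an estimator of
implicit adaptation, equal to $-\hat{x}$) is at least as large as the
peak drift — a signature that distinguishes it from accounts in which
adaptation stops once the participant re-conceptualizes the task.

`simulate_model()` exposes five variants: `standard` (no strategy),
`feedthrough_target_error` (feedthrough, learning from target error — no
drift, a useful null), `feedthrough_fixed_strategy` (aiming-error
learning at full certainty), `feedthrough_fixed_strategy_K` (same with
the availability weight), and `full_dynamic` (Eqs above, the variant that
is fit to data).

### Conventions and gating rules

* The instructed strategy engages at the start of the
  rotation-plus-strategy block ($s$ set to $s^\* = 45$) and is abandoned
  at washout ($s$ reset to 0). The strategy-adjustment dynamics run only
  inside that block.
* No-feedback trials freeze both states; they probe $\hat{x}$ without
  inducing learning.
* During strategy-only *practice* (veridical feedback), the cursor
  appears exactly at the hand, so the aim-referenced learning error is
  $-\hat{x}$ regardless of landmark availability: $K$ only matters once
  the rotation dissociates cursor from hand. Without this gating, groups
  with $K < 1$ would spuriously adapt $\sim 10^\circ$ during practice and
  enter baseline biased, which is not what is observed (and the practice
  block is excluded from fitting in any case).
* Hand angle and target error differ by exactly the rotation,
  $h_n = e_n - r_n$.
* Angles are double-precision degrees with no wrap-around handling;
  trajectories stay far inside $\pm 180^\circ$.
* Degenerate parameters ($A = B = 0$ etc.) are legal and give constant
  trajectories.

## The experimental protocol

`build_paper_schedule()` reproduces the 490-trial session the model is
meant for: 40 familiarization / 40 strategy-only practice / 40 baseline /
2 rotation probes (rotation on, strategy not yet instructed) / 320
rotation-plus-strategy / 8 no-feedback aftereffect trials (one per
target) / 40 washout. Eight target directions ($22.5^\circ + k \cdot
45^\circ$) are balanced within every block as seeded random permutations
per 8-trial sub-cycle; the original randomization scheme is not on
record, so a per-cycle balanced permutation was chosen (it guarantees
equal counts in every block whose length is a multiple of 8, including
exactly one trial per direction in the aftereffect block).
`build_custom_schedule()` builds variants such as the
120-baseline/322-rotation layout used for pure simulations.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` produces the study design: 3 groups × 10
participants, with per-group reference parameters (shared $A = 0.991$,
$B = 0.012$, $E = 0.999$; $K = 0.985/0.409/0.195$ and
$F = 0.023/0.002/0.725$ for AT/DAT/NoAT). The generative model is
**observation noise only**: states evolve on the noiseless path and the
observed target error adds iid Gaussian motor noise (default SD
$4^\circ$, chosen so that block-level variability is of the order
reported for this task; process noise is out of scope). Rare outlier
trials (rate 0.005) implement the occasionally observed
wrong-direction strategy: the strategy contribution is negated on an
instructed trial. Between-subject heterogeneity is truncated-Gaussian
jitter on the parameters, clipped to $[0,1]$, with SDs scaled to each
parameter's working range (0.003 for $A$ and $B$, 0.001 for $E$, 0.05
for $K$, 0.02 for $F$): drift over a 320-trial block is extremely
sensitive to retention factors sitting within 0.01 of 1, and these
scales keep the between-group drift ordering (AT > DAT > NoAT) intact,
which is the structure the groups are defined by.

Passing tests on such cohorts therefore show that the pipeline recovers
structure *of this generative form*; real data add process noise,
non-stationary strategies (abrupt re-aiming), online corrections and
target-direction biases that the generator deliberately omits.

## Fitting

`fit_single()` and `fit_groups_shared()` minimize the RMS error between
observed and predicted target error over the baseline, rotation-probe,
rotation-plus-strategy, aftereffect and washout blocks (familiarization
and strategy-only practice are excluded). Goodness of fit is reported as
RMS and Pearson's $r$ between predicted and observed *hand angles* over
the fitted trials. The shared fit constrains $A, B, E$ across groups
with per-group $K, F$; `bootstrap_fit()` resamples participants with
replacement within group (default 1000 resamples), refits the group
averages, and reports bootstrap means, percentile 95% CIs, and two-sided
contrast p-values $p = 2\min(\Pr(\Delta \le 0), \Pr(\Delta \ge 0))$ with
+1 smoothing.

Numerical choices, made once and kept:

* **Bounds.** All parameters in $[0,1]$, $K$ in $[0.1, 1]$ — the lower
  bound keeps the simplex away from a $K = 0$ local minimum that traps
  fits to low-drift groups. Bounds are enforced by a smooth logistic
  reparameterization (searching an unconstrained space and mapping back),
  because hard clipping creates flat regions that stall the simplex.
* **Optimizer.** Nelder–Mead with relative tolerance $10^{-8}$ on the
  loss, 5000 iterations per pass, restarted from the best vertex until
  the loss stalls (max 10 restarts). Because the loss surface has
  genuine local minima (an $A \to 0$ basin from the all-zero start, the
  $K = 0.1$ trap, and a high-$F$ ridge for NoAT-like series), each fit
  additionally runs from a small deterministic start set — the
  configured start (zeros, the study's choice), the mid-bounds point,
  and two high-retention starts with low and high $F$ — and keeps the
  best final vertex. On noiseless series this recovers all generating
  parameters to $<10^{-3}$.
* **Warm starts.** The joint fit is initialized from per-group single
  fits; bootstrap refits start from the full-sample solution (a ~25×
  speedup that leaves noiseless results unchanged).
* **Pearson's $r$** is computed on the raw fitted-trial series, not on
  binned data.
* A fit that exhausts all restarts without stalling is returned with
  `converged = FALSE` rather than raising an error.

A caveat that matters when interpreting recovery studies: the fit
targets the *group-averaged* series. Averages of heterogeneous nonlinear
trajectories are not the trajectory of the average parameters, so with
between-subject jitter the generating group means are not exactly the
estimand; recovery is unbiased in the homogeneous (no-jitter) case, and
parameters near their bounds ($E$, and $F$ for the near-zero-adjustment
group) have percentile CIs that collapse against the bound.

## Behavioral statistics

`remove_outliers()` drops trials whose hand angle is more than 3 SDs
from its block mean (single pass; blocks with fewer than 3 trials are
left alone with a warning — on the default protocol the 2-trial probe
block always triggers it). `bin_series()` averages 10-trial bins per
block, keeping the rotation-onset pair (the 2 probes) and the
strategy-onset pair (first 2 strategy trials) out of the bins as
separately averaged pairs. `peak_drift()` bootstraps the group average
and takes the most clockwise-positive bin (ties broken by the earliest
bin; "largest deviation" is read as most-CW, the direction of drift),
reporting the bin-center movement number counted from rotation onset.
`peak_drift_by_direction()` uses 10 bins of 4 movements per target
direction. `aftereffect()` averages the first 8 no-feedback trials.
`washout_rate()` fits $e_t = a\,e^{-\lambda t}$ ($t = 1, 2, \dots$
within the washout block, $\lambda \ge 0$, no offset term) to each
resampled group average by least squares; an amplitude indistinguishable
from zero is flagged unidentifiable with an infinite CI. The washout
series is the feedback washout block only — the no-feedback aftereffect
trials are not part of the decay series. All bootstrap estimators report
the mean of the resample statistics with percentile 95% CIs, and
participant order is canonicalized before resampling so estimates do not
depend on list arrangement.

## Problem sizes used in the tests

The shipped test-suite exercises the full pipeline at sizes chosen to
keep a complete run around a minute while still being informative:
parameter recovery on noiseless 490-trial series (exact), the drift
ordering on 100 seeded default cohorts (the acceptance property) and 20
more in the generator's own tests, bootstraps of 25–200 resamples, and
recovery-bias checks on 3 homogeneous noisy cohorts. The defaults users
see (`n_boot = 1000`) match the original analysis.

## Known limitations

* Strategy changes are modeled as a smooth linear adjustment; abrupt,
  categorical re-aiming (which some participants show) is outside the
  family, as are reinforcement-learning or task-reconceptualization
  accounts.
* Single implicit state: no fast/slow two-rate decomposition.
* The generator does not simulate 2-D trajectories, movement durations
  or online corrections; inputs are endpoint angles.
* The washout exponential carries no offset; series that decay to a
  nonzero plateau will bias $\lambda$ downward.
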