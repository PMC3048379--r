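# setpointadapt

Setpoint state-space models of visuomotor-rotation adaptation under an
explicit aiming strategy: simulation, synthetic-cohort generation, bounded
simplex fitting with a participant-resampling bootstrap, and the standard
behavioral statistics (peak drift, aftereffect, washout rate).

## The scientific problem

In a visuomotor rotation task, cursor feedback is rotated (here by
r = −45°, counter-clockwise) relative to the hand. If participants are
*told* the fix — "aim at the landmark 45° clockwise of the target" — they
compensate immediately. Paradoxically, with continued training their
movements then *drift* further clockwise, so endpoint errors grow again in
the direction of the strategy. The drift is attributed to implicit
adaptation of an internal model whose error signal is referenced not to
the target but to the *aiming location* (the setpoint). The strength of
the drift depends on how available that aiming location is: largest when
aiming landmarks stay visible (AT group), smaller when they vanish at
movement onset (DAT), and near zero when they are never shown (NoAT).
With long training, participants also re-aim to cancel the accumulating
error.

`setpointadapt` implements this model family for researchers in
sensorimotor learning who want to simulate, fit, or power-analyze such
experiments. With `x̂_n` the internal model's estimate of the rotation and
`s_n` the strategy state (degrees, CW positive, all per movement `n`):

    target error   e_n  = r_n − x̂_n + s_n            (direct feedthrough)
    aiming error   ê_n  = r_n − x̂_n + (1 − K)·s_n    (setpoint-referenced)
    internal model x̂_{n+1} = A·x̂_n + B·ê_n
    strategy       s_{n+1}  = E·s_n − F·e_n           (while in use)

`A` and `E` are retention factors, `B` the adaptation rate on the aiming
error, `K ∈ [0,1]` the availability/certainty of the aiming location, and
`F` the rate at which the strategy is re-adjusted by target error. With a
fixed strategy and full availability (`K = 1`, `F = 0`, `A = 1`) the drift
asymptotes at the full strategy magnitude (45°); `K < 1` attenuates it
proportionally; `F > 0` lets the strategy offset it. Model variants without
feedthrough or with target-error-driven learning are included for
comparison, as is the closed-form steady state.

## Worked example

```r
library(setpointadapt)

## deterministic simulation of the AT condition
sched <- build_paper_schedule("AT")              # 490-trial protocol
p     <- group_params_default("AT")              # A=0.991 B=0.012 E=0.999 K=0.985 F=0.023
tr    <- simulate_model(sched, p, "full_dynamic")
fixed_point(p)                                   # pseudo-equilibrium

## a synthetic cohort (10 participants/group) and its behavioral statistics
cohort <- generate_cohort(cohort_config(seed = 1))
at     <- split_by_group(cohort)$AT
peak_drift(at, n_boot = 200, seed = 1)
aftereffect(at, n_boot = 200, seed = 1)
washout_rate(at, n_boot = 200, seed = 1)
```

Output (abridged):

```
$x_hat             $s                $e
-25.55             18.64             -0.81

AT peak drift 10.0 deg, 95% CI [6.5, 14.4], at movement 78
AT aftereffect 26.1 deg, 95% CI [23.4, 29.8]
AT washout lambda 0.018 per trial, 95% CI [0.015, 0.023]
```

Read: at equilibrium the internal model has over-adapted past the point
the strategy compensates (x̂ ≈ −25.6°) while the re-aimed strategy
(s ≈ 18.6°) keeps the target error near zero. In the synthetic AT cohort
the group's drift peaks ~10° clockwise about 78 movements into the
rotation block; the aftereffect (~26°, the implicit adaptation left when
rotation, strategy and feedback are removed) exceeds the peak drift, the
model's signature prediction; and the washout block decays with rate
λ ≈ 0.018 per trial, which in the model depends only on `A` and `B` —
never on `K`, since the strategy is abandoned before washout.

Model fitting mirrors the original analysis: the five parameters are
bounded in [0, 1] (`K` in [0.1, 1]), `A`, `B`, `E` are shared across
groups while `K` and `F` are per-group, and uncertainty comes from
resampling participants with replacement and refitting the group average:

```r
fit <- bootstrap_fit(cohort, fit_config(n_boot = 1000, seed = 1))
fit$estimate    # bootstrap means, e.g. K_AT > K_DAT > K_NoAT
fit$contrasts   # two-sided bootstrap p-values for K and F contrasts
```

A thin command-line wrapper is installed under
`inst/scripts/setpointadapt-cli.R` (stages `simulate`, `fit`, `analyze`,
`all`); every run writes a manifest with the master seed and config hash
so outputs are bit-reproducible.

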