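---
title: "Sleep as a choice: model, conventions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep as a choice: model, conventions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcost)
```

## The model and its assumptions

`sleepcost` simulates sleep timing as a sequence of myopic binary choices.
The animal carries two state variables through ten-minute periods: sleep
pressure `H` (the homeostat) and an AR(1) environmental state `z` that
scales the return to waking activity. A single cosine `y_t = -cos(2πt/q)`
represents the circadian cycle, lowest at midnight and highest at midday,
which makes night the cheap time to hold a low homeostat — i.e. to sleep.

Each period the animal compares exactly two candidate one-period utilities
and takes the better one (ties keep the previous action):

* **wake**: foraging utility `[e^z ξ (μ_W − H)^η]^γ` computed at the
  *incoming* stock of sleep pressure, minus the circadian penalty
  `χ|H^w − y|^κ` at the wake-updated homeostat;
* **sleep**: no foraging utility, minus the penalty `χ|H^s − y|^κ` at the
  sleep-updated homeostat;
* either branch pays the fixed switching cost `λ` if it changes state.

Assumptions worth keeping in mind: the choice is strictly one period ahead
(no dynamic programming), sleep is a binary state with no internal stages,
and all environmental variation is the scalar `z`. The classic two-process
threshold model ships alongside (`simulate_classic()`) both as a baseline
and because it is the `κ → ∞`, fixed-opportunity-cost limit of the choice
model; `test-decision.R` exercises that limit at `κ = 40`.

## Parameters

| field | meaning | unit | shared preset value |
|---|---|---|---|
| `q` | periods per day | count | 144 (10-minute periods) |
| `kappa` | circadian-penalty curvature | — | 2 (quadratic) |
| `eta` | foraging-production curvature | — | 1 |
| `gamma` | foraging-utility curvature | — | 0.8 |
| `rho` | persistence of `z`, per hour | — | 0.9 |
| `nu_W`, `nu_S` | homeostat e-folding constants | hours | 8 |
| `mu_W`, `mu_S` | waking/sleeping asymptotes | homeostat units | species-specific |
| `lam` | switching cost | utility | 0.2 |
| `chi` | circadian-penalty weight | — | 10 |
| `xi` | opportunity-cost scale | — | 1 (captive), fitted (wild) |
| `sigma` | innovation SD of `z` | z units | fitted |

Presets are data, not code: flat JSON files under `extdata/presets/` with
keys exactly equal to the field names (unknown keys are rejected to catch
typos), so new species files can be copied and edited. `λ` controls
polyphasy — too high and the animal monophases or never sleeps, too low and
it micro-cycles; 0.2 produces realistic episode counts for both shipped
species. `χ` sets how binding the circadian cycle is relative to foraging.

## Unit conversions: two deliberate choices

**Homeostat decay.** `nu_W`/`nu_S` are quoted in hours and converted once,
in `decay_factor()`, to the per-period factor `exp(-24/(ν q))`, i.e. the
constants are e-folding times (the update applies `e^{-1/ν̃}` directly).
Treating them instead as ln 2-scaled half-lives would slow the homeostat by
~44% and visibly degrades the elephant benchmark (the stylized day drops
from four sleep episodes to two), so the e-folding reading is the default
and only convention used by the package; the alternative is one argument
away (`decay_factor(nu / log(2), q)`).

**Environmental persistence.** `rho` is quoted per hour. With `q/24`
periods per hour the per-period AR coefficient is `ρ^{24/q}`
(`rho_convention = "per_hour"`, the default). The alternative reading
`ρ^{1/q}` ("per_day_root", also implemented) makes the *daily* persistence
0.9 and inflates the stationary SD of `z` by a factor of ~4; under it the
wild-elephant simulation overshoots the observed mean sleep by almost a
factor of two, while the per-hour reading reproduces the reference moments
to within ~2%. Both conventions are selectable in `simulate_sleep()` and
`calibration_spec()`; everything shipped uses per-hour.

## Decision-rule conventions

Three notational choices are baked in and documented here because plausible
alternatives exist:

1. `A = 1` means asleep everywhere, and the foraging term is active when
   *awake*. (The mirrored reading — foraging utility while asleep — makes
   the model degenerate: the animal locks into permanent sleep.)
2. `χ` multiplies the circadian penalty, not the foraging term; this is the
   weighting the shipped calibrations are defined under.
3. Exact utility ties keep the previous action: any infinitesimal switching
   cost resolves ties that way, and it keeps trajectories deterministic.

## Simulation numerics

* **Initial conditions.** `H0 = 0`, awake, `z0 = 0` (the unconditional
  mean), starting at a midnight phase. The homeostat update is a
  contraction and `z` mean-reverts, so initial conditions wash out
  geometrically; the default 10-day burn-in is discarded before any
  statistic.
* **Update order.** Within a period `z` advances first, then the choice is
  made seeing the current-period `z` and `y`.
* **Randomness.** All draws come from an explicit `draw_bank` (seeded,
  reproducible, never touching the caller's RNG state); a given bank maps
  to a bit-identical trajectory. The compiled kernel and the R-level
  per-period primitives (`choose_action()` etc.) are tested against each
  other period by period.
* **Stylized days.** `simulate_stylized()` runs the noise-free model and
  looks for the smallest `k ≤ max_period` (default 8 days) such that
  consecutive `k`-day blocks match exactly in actions and within `1e-9` in
  `H`. The elephant presets converge to one-day cycles within ~10 days; the
  wild-sloth preset converges to an exact *four-day* cycle, which is why
  the detector generalizes beyond single days (episode counts are then
  reported per day of the cycle). Non-convergence raises a condition
  carrying the last two days for inspection.
* **Episode counting.** Episodes are maximal asleep runs, attributed to the
  day they start in; on a stylized cycle the series is treated as circular
  so a run spanning the cycle boundary counts once.
* **Daily SD.** Population formula (divide by the number of days) — at
  10⁴–10⁵ days the distinction from the sample formula is far below every
  tolerance used.

## Calibration design

Free parameters (captive: the unnormalized asymptote plus `σ`; wild: `ξ`
and `σ`) are chosen to minimize `|mean − target| + |SD − target|` in hours,
with one fixed draw bank shared by every objective evaluation (common
random numbers — the objective is deterministic, so Nelder–Mead sees a
smooth-enough surface and two evaluations at one point are bit-identical).
Candidates that violate the parameter invariants get a large finite penalty
that grows with the violation, keeping the simplex feasible without
exceptions. Starting points: a free asymptote starts at its preset value
with `σ = 0.01`; the wild pair starts at `ξ = 5`, `σ = 0.1`. One restart
from the best point if the first pass fails to converge; 500 evaluations
per pass. The default 20,000 simulated days per evaluation keeps a full
calibration around half a minute on one core while leaving moment noise
well below the fitting tolerances; pass a larger `sim_days` (e.g. 100,000)
for publication-scale runs.

Synthetic-recovery tests simulate moments at known `(ξ*, σ*)` and refit on
the same bank; the acceptance suite checks a five-point grid with median
relative error below 5%.

## What the simulator does and does not emulate

The model generates realistic polyphasic structure, captive/wild contrasts
driven purely by `ξ` and `σ`, and day-to-day variability from a single
persistent scalar shock. It does not represent sleep stages, naps driven by
social context, seasonality, weather, or measurement error in field
recordings — so matching the shipped moments shows the *mechanism* is
sufficient for those aggregates, not that real recordings would validate
every trajectory-level feature.

## Known limitations

* The wild-sloth preset is internally tense: forward simulation at its
  shipped `(ξ, σ)` lands ~9% below its own target mean, and refitting
  recovers `ξ ≈ 5.1` rather than the shipped 6.283. The sloth reference
  values are kept as-is; treat the elephant presets as the cleaner
  benchmark. (Flipping the sign of the sloth `mu_S` to +1 brings the wild
  column — episodes, moments — into close agreement but breaks the captive
  column; no single sign fixes both, so the package keeps `mu_S = -1`.)
* In both the classic and the generalized model, shifting *both* homeostat
  asymptotes upward lengthens sleep (the sleeping branch decays toward a
  nearer target, the waking branch rises faster); the classic tests pin
  this direction against the closed-form phase durations.
* The myopic rule cannot anticipate — e.g. pre-sleeping ahead of a
  predictable high-cost window; a forward-looking extension is out of
  scope.
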