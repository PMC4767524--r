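---
title: "Motion-guided attention in social prey: model, experiment machinery, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-guided attention in social prey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preyswarm)
library(dplyr)
```

preyswarm simulates groups of self-propelled prey whose coordination emerges
from a visual sensory mechanism — selective attention to neighbour motion —
and wraps that model in the machinery of a predator-targeting experiment:
a factorial trial design, seed-replayed veiled/visible trial pairs, a
scripted surrogate predator with capture scoring, per-trial kinetic metrics,
and the data-preparation pipeline for a mixed-model analysis of capture
latency and accuracy. This vignette is the package's own account of the
model, its assumptions, and the design decisions taken where the design was
genuinely open.

## The movement model

Each of *n* prey is a point agent in the plane with position `x_i` (units of
body diameter *D*), speed `v_i` (*D* per step; one step = one rendered frame
= 20 ms), and unit heading. Every step proceeds in five synchronous phases.

**1. Visual perception.** The influence of neighbour *j* on observer *i* is
weighted by apparent motion — the magnitude of relative velocity scaled by
optical distance:

omega_ji = |v_j − v_i| / max(d_ij, D).

A neighbour moving identically to the observer produces no optic flow and
has zero weight; at fixed relative speed the weight decays with distance.
The denominator is clamped at one body diameter so near-collisions do not
produce unbounded cues. All other group members are perceived (a 360° visual
field with no occlusion — the prey see each other and nothing else, and
never react to the predator).

**2. Weber-law attention.** Observer *i* attends to the set **N**_i of
neighbours whose cue stands out against the mean optic flow
`omega_bar = mean_j(omega_ji)`:

j ∈ **N**_i iff omega_ji / omega_bar ≥ m.

The social threshold *m* is the model's central knob: what counts as salient
is a *proportion of the background*, the signal-to-noise form of Weber's
law. At `m = 0` every neighbour is attended (whenever the field is
non-degenerate); large *m* (the study uses 10 as its asocial extreme,
approximating a flash expansion) leaves attention nearly empty. If the mean
flow is exactly zero nothing can stand out and the set is empty.

**3. Social velocity.** The attended relative motion is pooled into a
desired velocity:

v_i^s = v_i + ⟨ omega_ji · u_ji ⟩_{N_i},

where `u_ji` is the unit direction of neighbour *j*'s motion *relative to*
the observer, `u_ji = (v_j − v_i)/|v_j − v_i|`. The product simplifies to
`(v_j − v_i)/max(d_ij, D)`: each attended neighbour pulls the observer's
velocity towards its own, scaled by optical distance. The term is
consensus-seeking and vanishes once the group moves as one.

*Why the relative-velocity reading?* The alternative — pooling each
neighbour's absolute heading — was implemented and rejected: it adds a
strictly positive along-track component at every step, so group speed
equilibrates well above the energetic optimum and never converges to `v*`,
contradicting the model's own premise that social interaction shapes the
*transient*, not the final cruise speed. Velocity-difference matching
restores that property and matches the description of the pooled quantity
as *relative* motion.

**4. Travel-cost speed regulation.** Speed is regulated around an expected
optimum `v* = 0.44 D/step` by a signed linear cost

gamma(v) = phi · (v − v*) / v*,  phi = 0.1,

clamped to (−0.9, 0.9), applied as multiplicative Langevin-style dampening:

v_i(t+Δt) = |v_i^s| · (1 − gamma(|v_i^s|)).

Below `v*` the cost is negative and the agent accelerates; above, it
decelerates. The fixed point at `v*` is stable (local contraction factor
`1 − phi = 0.9`, so an isolated agent started at the 0.1 floor closes to
within 0.001 of `v*` in well under 200 steps). The cost is linear in speed
by design — the simplest form with the documented sign structure and a
stable optimum; the clamp guarantees the dampening can never reverse or
null a velocity. We read the update as multiplicative dampening rather than
a power law; the dampening reading is the one consistent with its
social-force (Langevin) lineage and produces the documented smooth
relaxation of a startled individual back to `v*`.

**5. Noise, turning limit, position.** Speed is perturbed by an independent
uniform factor in `[1 − eta, 1 + eta]` and heading rotated by an independent
uniform angle in `[−eta·π/2, eta·π/2]` (`eta = 0.1` by default; fully
configurable — the value is a package default chosen inside the documented
`[0, 1]` range, moderate enough that groups still order at low *m* yet
disordered groups stay disordered at *m* = 10). The turning limit π/2 per
step is applied to the *combined* social + noise heading change, so noise
cannot smuggle in turns the limit would forbid. Positions then advance by
`v·Δt`, and any pair closer than one body diameter is pushed apart
symmetrically along its line of centres to exactly *D* (near-collisions
separate sharply, as they should; there are no other attraction/repulsion
zones). Speeds are clamped to `[0.1, 1.5] D/step` after every full step.

All agents update synchronously from the time-*t* state (parallel update);
per-agent random draws happen in fixed agent order, which together with one
seeded generator per trial makes every trajectory bit-reproducible.

### What the model does at steady state

With noise on, the replicate-mean cruise speed computed by the package's
own suites settles a few percent *below* `v*`, most visibly at the lowest
thresholds: consensus averaging pulls each velocity towards the group mean
velocity, whose magnitude is strictly less than the mean speed whenever
headings disperse. The effect is inherent to velocity-consensus models, and
the experiment's own rendering constants embody it — the scenario
documentation's nominal cruise speed (0.400 *D*/step, i.e. 0.46 cm/s on
screen) sits below the individual optimum 0.44 for exactly this reason.
Polarization falls steeply as *m* rises, and from disordered starts the
time for the group to reach 90% of `v*` is far longer for attentive prey
(low *m*) than for asocial prey — the departure lag — while ordered starts
largely erase that difference. These are the phenomenological properties
the test suite asserts.

## Trials, sessions, and seed replay

A trial is defined by a `scenario_config()`: group size (25 in the
published design), the target's threshold `m_t` and the group's `m_g`
(levels 0.5/1.5/2.5/10), the target's initial escape factor `v_e` (1 or
10: on each of the first five frames the target's speed is multiplied by
`v_e`, then clamped — a ×10 burst saturates the 1.5 cap immediately),
the initial organization (disordered: i.i.d. uniform headings; ordered:
one global heading with ±0.175 rad of per-agent uniform wobble), the veiled
flag, and the seed.

Initial positions are placed uniformly, without overlap, in a centred disc
of radius 15 *D* (the placement is not documented upstream; this default
keeps initial nearest-neighbour distances inside the observed metric
ranges, and it is configurable). All agents start at the 0.1 *D*/step floor
and accelerate up toward cruise speed; the target is designated uniformly
at random from the trial's seeded stream.

`build_design()` enumerates the three-session factorial: session I
(homogeneous groups, `v_e` × *m* × organization = 16 cells), session II
(`m_t` × `m_g` × organization at `v_e = 10` = 32 cells, of which the 8
homogeneous ones coincide with session I and are counted once), and
session III (veiled replicates of all 32 session II cells). With two
replicates per unique cell this is exactly 144 trials. Veiled trials copy
the seed of their matching visible trial; because the veiled flag never
enters the dynamics code path, each pair replays bit-identical prey motion
— that is the manipulation that isolates the visual confusion caused by
neighbours from the target's own socially driven movement.

The printed initial-organization descriptors of the two modes (about 0.27
and 0.9) differ from the analytic time-zero expectations of the stated
initializations (≈0.18 disordered, ≈0.995 ordered, the latter being
sin(w)/w for uniform wobble ±w); they are plausibly measured a few frames
after release rather than at frame zero. The package treats the two init
modes as the factor and the time-zero values as consequences, not enforced
constraints.

## Kinetic metrics

`kinetic_summary()` computes, over a configurable window (default: the
whole recorded trial, i.e. up to capture or miss):

* `v_T`, `v_G` — target and group mean speed (D/step);
* `tor` — target path tortuosity, `1 − net displacement / path length`,
  on the step-resolved path: 0 for a straight run, 1 for a closed loop;
  undefined for a zero-length path (flagged, not fabricated);
* `rho` — polarization, the mean resultant length of headings;
* `vpa` — the target's Voronoi polygon area, clipped to the arena
  rectangle (unclipped outer cells are unbounded; the published pixel²
  ranges imply screen clipping). Cells are computed by exact half-plane
  (perpendicular-bisector) clipping of the arena rectangle — no external
  geometry library is involved — and are validated in the tests against a
  brute-force nearest-site grid oracle and the exact tiling identity
  (areas sum to the arena area);
* `nnd` — mean nearest-neighbour distance.

Per-frame series of the same quantities are attached for time-series
output, via `kinetic_series()`.

## Capture scoring

`surrogate_predator()` is a scripted stand-in for the human player — a test
fixture, not a behavioural claim. It pursues the target's position as
perceived `visual_delay` ms earlier (default 125 ms, inside the documented
100–150 ms human visual-response band), after an initial motor-delay
immobility (default 300 ms), with proportional gain, a cursor speed bound,
and seeded jitter. A trial ends with a click (cursor within `click_radius`
of the perceived target), the target escaping off-screen (a miss), or the
trajectory ending.

Scoring follows the analysis-side transforms: latency is natural-log
transformed (`P_L = ln ms`; the published `P_L` range [6.2, 8.4] brackets
the printed 240–5,767 ms trial durations precisely on the natural scale,
which is why the package fixes `ln` rather than `log10`), and accuracy is
`P_A = 1 − log(d_T + 1)/max(log(d_T + 1))`, the maximum taken over the
analysis dataset (a direct hit scores 1, the worst recorded click exactly
0). The normalizing maximum is attached to every score table, because `P_A`
is only interpretable relative to it; whether the upstream analysis
normalized per session or globally is not documented, so the package
normalizes over whatever set of records is scored together and records the
constant. Misses where the target reached the boundary are edge-corrected:
the capture point becomes the cursor position at the boundary-crossing
frame, the latency the crossing time.

## Analysis preparation

The package prepares, but does not fit, the mixed-model analysis (fitting
is standard and belongs to lme4 or equivalent):

* thresholds enter as `L(m) = log(m + 1)`;
* kinetic metrics are standardized to zero mean, unit variance (the
  conventional z-score; a garbled rendering of the transform upstream is
  read as `(z − z̄)/s_z`, the only form consistent with "scaled to unit
  variance");
* `screen_collinearity()` flags metric pairs with Spearman |r| > 0.5,
  replaces the worse-fitting member (single-predictor AIC against the
  response; ties break in favour of the first metric in column order) with
  its residuals on the better one, and re-checks that all VIFs are ≤ 2.6.
  Residualized columns are exactly orthogonal to their reference.

A typical downstream fit on the prepared table is
`lme4::lmer(P_L ~ L_m_t * init_mode + v_T + tor + vpa + v_G + nnd + (1 | player), data = tbl)`
followed by backward elimination of non-significant terms; that path
depends on the fitting engine and is deliberately out of scope here.

## Numerical choices and degenerate inputs

* Coincident Voronoi sites are perturbed by 1e-9 with a warning so every
  cell is well defined; coincident prey positions in the weight function
  are handled by the distance clamp at *D*.
* A zero social velocity keeps the previous heading and relaxes speed from
  the floor through the cost rule — no division by zero, no special-cased
  trajectory.
* The travel-cost clamp (−0.9, 0.9) keeps the multiplicative update
  orientation-preserving at any speed in and beyond the bounds.
* Zero-variance columns refuse to standardize (named error); a constant
  reference predictor refuses to residualize; perfect collinearity reports
  an infinite VIF rather than a misleading large number.
* Two engines implement the stepper — a plain-R reference and a compiled
  fast path — consuming the RNG in the identical draw order; the suite
  checks them against each other at 1e-9 and checks bit-exact replay
  within each engine. Cross-engine agreement is held to a numerical
  tolerance rather than bit identity because R's vectorized accumulators
  use extended precision.

## Problem sizes in the shipped suites

The test and acceptance suites run the published group size (25) at full
trial lengths where a claim depends on it — steady-state speed uses 100
replicates × 1000 steps per threshold; polarization contrasts use 200
replicates per threshold at 300 steps; departure-lag contrasts 40
replicates per condition at 250 steps. Smaller groups (6–15) and shorter
runs are used for contracts that do not depend on scale (replay, bounds,
round-trips). These sizes are the package's own choices, balancing
statistical resolution of the asserted contrasts against suite runtime.

## What the generator does and does not emulate

The synthetic scenarios reproduce the study conditions: factor levels,
group size, initialization, burst, render-scale constants, and seeded
veiled/visible pairing. They do not emulate human players (the surrogate
predator is deliberately simple and its parameters are fixtures), screen
rendering, player learning or order effects, 3-D motion, occlusion, or
predator-aware prey — the prey cannot respond to the attack by
construction. Passing suites therefore validate the model's mechanics and
the experiment plumbing, not any claim about human capture behaviour; the
human-subject statistics of the original study are explicitly not
reproduction targets.

## Known limitations

* The exact upstream forms of the perception weight and the travel-cost
  function are not public; the package's declared forms (`|Δv|/max(d, D)`
  and the linear signed cost) satisfy every documented property but are
  not guaranteed to be identical. The weight function is a configurable
  hook at the reference-engine level for swapping alternatives.
* Under the distance-scaled weight, coordination is highest at `m = 0`;
  the upstream description has coordination *peaking* at small positive
  *m* because unconstrained sensory range admits distant, uncorrelated
  neighbours. Reproducing that nuance would require a weight that decays
  more slowly with distance.
* Steady-state mean speed sits slightly below `v*` at low thresholds
  (consensus shrinkage, above); analyses that need the nominal cruise
  speed should measure it, as the acceptance script does.
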