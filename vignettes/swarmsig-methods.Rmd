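---
title: "Signal-based swarming: model, evolutionary dynamics and measurement methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-based swarming: model, evolutionary dynamics and measurement methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmsig)
```

## The model

`swarmsig` simulates a population of agents foraging in a cubic toroidal
arena of side 600 (arbitrary length units, periodic boundaries on all three
axes).  A single resource site sits somewhere in the arena; agents cannot
sense it.  Their only sensory input is *signaling*: every agent emits a
scalar intensity in [0, 1] and carries six directional sensors (front, rear,
left, right, top, bottom).  Each emitter within toroidal distance 100
contributes `intensity / max(d, 1)` to the receiver's sector nearest the
minimal-image direction of the source; each sector is clipped to [0, 1].
Swarming — if it evolves — must therefore be built entirely out of reacting
to neighbours' signals.

Each agent is steered by a recurrent neural controller with 6 inputs (the
sector sensors), 10 logistic hidden units, 10 logistic context units fed
back Elman-style, and 3 outputs: two motor outputs mapped affinely onto yaw
and pitch angles in [-pi/4, pi/4], and the emitted signal intensity.  The
controller has `6*10 + 10*10 + 10*10 + 10*3 = 290` weights in [-1, 1], each
encoded by one gene in [0, 1] (`weight = 2 gene - 1`).  Agents move at
constant speed 1: the velocity update adds `tan(yaw)` along the body-frame
right axis and `tan(pitch)` along the body-frame up axis and renormalises.

Evolution is asynchronous (steady-state): there is no generation clock.
Every iteration each agent pays a survival cost `c * 0.01` and a signaling
cost `c * 0.001 * intensity` (with `c` a global cost factor), and absorbs
`min(r / d, 1)` energy from the resource at plain Euclidean distance `d`.
An agent reaching 10 energy units pays 8 to place a mutated replica (energy
2, per-gene mutation probability 0.05, uniform offset within ±0.05) at a
uniform random position; an agent at zero energy, or older than 5000
iterations, is removed.  A homeostat nudges `c` (×1.0001 above 250 agents,
÷1.01 below 150) to hold the population near 200 inside hard bounds
[100, 1000].  The resource site relocates uniformly every 5000 iterations.

Runs come in two modes.  *Training* runs the full dynamics above.
*Testing* freezes the population: the resource term is replaced by a
per-agent allowance exactly covering costs, and reproduction, death and the
homeostat are off.  Two perturbation protocols are provided: global
*silencing* (`silenced = TRUE`) forces every emitted intensity to zero, and
*freerider injection* (`inject_freeriders()`) silences k randomly chosen
agents by zeroing the genes of the ten hidden-to-signal-output weights
(decoding to the saturating weight -1) and additionally forcing their
emitted intensity — and, by inheritance of the flag, their descendants' —
to exactly zero, since bounded weights alone cannot make a logistic output
vanish.

## Parameters the publication leaves open

Four quantities needed by an implementation are not stated anywhere in the
source material; this package fixes them as follows and treats them as part
of the study conditions.

**Sigmoid slope (`beta`)**: 1.0.  Any slope can be absorbed by rescaling
the evolved weights, so the choice mainly sets the scale of the initial
random policies; 1 is the conventional default.  Context units pass through
the same logistic as everything else: the 290-weight count requires
trainable hidden-to-context weights, and a uniform nonlinearity is the
simplest consistent reading.

**Reward scale (`reward`, default 10)**: the gain law `min(r / d, 1)` needs
a magnitude.  The default makes agents within 10 units of the site absorb
at the cap of 1 energy per iteration, and puts an agent at the mean
random-wander distance (0.6617 × 600 ≈ 397 units, the mean point-pair
distance of a cube) at a gain of ≈ 0.025 per iteration — comfortably above
the base survival cost at unit cost factor, so the population homeostat,
not starvation, is what limits growth.

**Initial cost factor (`cost_factor0`, default 3.0)**: chosen so that the
population-mean energy influx of a uniformly dispersed population,
`r · E[1/d] ≈ 10 × 1.882 / 600 ≈ 0.031` per iteration, balances the scaled
base cost `c · 0.0105` at `c ≈ 3`; runs then start near aggregate energy
balance rather than in free growth or mass starvation.

**Founder energies**: drawn uniformly between the newborn energy (2) and
the replication threshold (10).  A founding cohort with identical energy
dies (or replicates) in near-synchrony a few hundred iterations into the
run, which kicks the homeostat hard at start-up; spreading the initial
energies desynchronises the cohort.  Newborns during the run always start
at exactly 2, as specified.

## Per-iteration semantics

All agents sense the *previous* iteration's positions and signals, so
within-iteration results do not depend on agent order.  The fixed stage
order is: sense; step controllers; update velocities, then positions; set
emitted signals to the third controller output; energy ledger; reproduction
(children are appended and do not act in their birth iteration);
culling (suppressed at or below the population floor, in agent-index
order); homeostat; resource relocation; ageing.  Agents are silent
(intensity 0) until their first controller step.

The energy ledger is auditable: logged gains are net of the 100-unit energy
cap, energy removed by deaths is logged, and the per-iteration identity
`delta(total energy) = gains - costs - 6 * births - removed_by_death`
(births transfer 8 from the parent and create a child with 2) holds to
machine precision.  This identity is asserted in the test suite.

Both costs enter the fitness flow as expenditures
(`gain - c * (C_mov + C_sig)`).  The source material prints a minus sign
between the two cost terms in one place, which would make signaling a
rebate; that contradicts the explicitly stated signaling *cost*, so the sum
is used.  Similarly, the printed population floor of 50 in one passage is
superseded by the tabulated value of 100, and the tabulated weight range
[-1, 1] supersedes a textual "between 0 and 1".

The printed output-to-angle conversion is internally inconsistent (it
defines the pitch twice, with an undefined constant); the package uses the
affine map `angle = alpha_max * (2 * output - 1)` with `alpha_max = pi/4`.
Any monotone map is behaviourally equivalent up to evolution rescaling the
weights; `alpha_max` is exposed because fast rotation is reported to matter
for swarming.  The published velocity update applies the pitch term along
the previous velocity, which renormalisation would annihilate (agents could
never leave a plane); the package applies it along the body-frame up axis,
the standard Euler-pitch reading.  The lateral direction of the yaw term is
fixed to the body-frame right axis.

Two distance conventions coexist deliberately.  Neighbour detection and
signal attenuation use the toroidal (minimal-image) metric — sensing must
be translation-invariant on the torus.  The distance-to-goal statistic and
the foraging gain use the plain Euclidean distance between stored
coordinates: the uniform-wander baseline of that statistic is then the mean
random point-pair distance of the cube, ≈ 397 units for side 600, matching
the reported control-run level of "around 400" (the toroidal mean, ≈ 288,
does not).

## Measurement machinery

**Neighbourhood**: `avg_neighbors()` is the mean number of other agents
within toroidal radius 100 — the swarming order parameter.

**Information flow**: `transfer_entropy()` is a discrete plug-in estimator.
Velocity series are symbolised by per-component equal-width binning (k = 2
bins per component by default) and composed into joint symbols; transfer
entropy conditions on a past block of length `h` at delay `d` (defaults
h = d = 1).  Binning (rather than a continuous nearest-neighbour
estimator) was chosen because it admits an exact brute-force oracle: the
test suite checks the estimator against a direct conditional-entropy
computation on every tested series, and checks that the copy channel
`Y_t = X_{t-1}` recovers `log k` within 2% at series length 1e4.
`inward_nte()` / `outward_nte()` sum pairwise transfer entropies over the
neighbour graph frozen at the window midpoint; inward (neighbours → self)
reads as "following", outward as "leading".  Estimates use natural
logarithms.  The window length, bin count and history are configurable via
`te_config()`; absolute values depend on these choices, so only
comparisons made with identical settings are meaningful.

**Genotypic diversity**: `genotypic_diversity()` discretises each of the
290 loci into 5 equal-width classes, computes the plug-in Shannon entropy
per locus in base 10, and sums over loci (units: hartleys; maximum
290 × log10(5) ≈ 202.7).  Whole-genotype frequencies would cap the measure
at `log10(population)` ≈ 3 hartleys, an order of magnitude below the
reported scale of tens of hartleys, so the per-locus reading is the only
consistent one.

**Other read-outs**: `distance_to_goal_stats()` (raw distances),
`response_surface()` (motor output over a grid of front-sensor × context
levels, one controller step from a fixed state), `pca_embed()`
(mean-centred PCA of genotypes, deterministic sign convention),
`mean_signal_intensity()`, and the lineage tools (`export_newick()`,
`fork_rate_series()`).  In the Newick export a parent's branch is
subdivided at each reproduction into a synthetic fork whose first child is
the continuing parent — Newick has no serial-reproduction primitive — and
branch lengths are iterations.

## The homeostat is a relaxation oscillator, not a regulator

The published control law adjusts the global cost factor by ×1.0001 per
iteration above 250 agents and by ÷1.01 per iteration below 150 — downward
relief about a hundred times faster than upward pressure.  The plant it
controls responds slowly in both directions: killing surplus agents
requires the cost factor to climb until accumulated energy reserves (up to
100 units per agent) drain, and restoring a collapsed population requires
survivors to re-accumulate the 10-unit replication threshold.  Both lags
are hundreds to thousands of iterations, while ÷1.01 halves the cost factor
every ~70 iterations.

The consequence, reproducible with this package at any reward magnitude and
from any starting point we tried, is a stable limit cycle rather than
regulation: the population spends most of its time at the hard cap of 1000
while the cost factor climbs slowly, then crashes through the band, the
brief sub-150 excursion slashes the cost factor by orders of magnitude, and
the cycle restarts (period ~5e4–1e5 iterations at the defaults).  The
time-averaged population of a training run is therefore near the cap
(~900–1000), not inside [150, 250].  The model's qualitative phenomenology
(wandering, signaling, selection around the goal) is unaffected — the cost
factor simply tracks its slow sawtooth — but any quantitative claim that
the time-averaged population sits inside the homeostat band is not
reproduced by these published rates under this package's (direct) reading
of them: one multiplicative update per iteration while outside the band.
We implement exactly that reading and report the measured average; the
control experiments that need a fixed ~200-agent population use the testing
protocol, which holds the population constant by construction.

## What desk-scale runs do and do not show

The package's own runs are the synthetic data: there is no external input.
A worked example at desk scale:

```{r example}
set.seed(1)
pop <- new_population(50)
res <- new_resource()
run <- run_simulation(pop, res, iters = 2000)
run
tail(run$stats[, c("t", "pop", "cost_factor", "mean_signal",
                   "mean_goal_dist")], 3)
```

The published phenomenology spans 1e5–1e7 iterations: the neighbour-count
take-off appears near 1e5 iterations, freerider takeover needs ~2e5
iterations after injection, and the genotypic-diversity minimum sits near
1e6.  Those are multi-hour computations and are *not* reproduced by the
test suite.  What the tests do establish, at 2e4–5e4 iterations on fixed
seeds: the silenced control wanders at the ~397-unit baseline distance, and
every exact property (ledger closure, speed conservation, estimator
oracles, architecture counts) holds to stated precision.  Two checks are
expected to fail and are kept failing deliberately: the time-averaged
population of a training run is not inside the homeostat band (previous
section), and matched 5e4-iteration signaling-on versus silenced runs do
not yet differ in the swarming direction — at that horizon no signal
response has evolved (the training run's density-corrected neighbour excess
is ~0.08, i.e. noise), and the raw neighbour counts of the two runs mostly
reflect their different population trajectories.  `excess_neighbors()`
(the count minus its uniform-density expectation) is the order parameter
robust to that density confound.  Passing the remaining checks says the
machinery is faithful at scale; it does not certify emergent long-run
behaviour, which remains stochastic and slow.

## Numerical choices and degenerate cases

* Coordinates live in the half-open cell [0, L); exactly L wraps to 0.
* Sector ties (a source exactly between two sensor axes) resolve in the
  fixed order front, rear, left, right, top, bottom.
* Attenuation is floored at distance 1 (`intensity / max(d, 1)`), so
  near-coincident emitters cannot produce unbounded pre-clip readings; a
  exactly-coincident emitter is assigned to the front sector by convention.
* "Normalized between 0 and 1" sensor readings are implemented as clipping
  each sector's sum: any population-wide rescaling would make a lone pair's
  readings depend on global state, contradicting local sensing.
* If steering exactly cancels the velocity (measure zero), the previous
  heading is kept; the speed-1 contract is asserted to 1e-9.
* A controller fed by an empty arena still steps (inputs all zero);
  an empty population steps as a no-op.
* Transfer entropy of a constant series is 0 with a warning; plug-in
  estimates are clipped at 0.
* The same RNG stream (R's, seeded by `set.seed()`) drives every random
  choice in a fixed draw order, so runs are bit-reproducible; the compiled
  engine and the pure-R reference step (`simulation_step()`) share that
  draw order and are cross-checked against each other in the tests.

## Known limitations

* The transfer-entropy parameters used for the published figures (history,
  delay, bins, window, sampling stride) are unknown; absolute NTE values
  are therefore not comparable with the printed curves, only their
  qualitative contrasts (on vs off, leader vs follower) are.
* Sensor rotation invariance holds exactly for rotations preserving the
  world vertical (the body frame is built from world-z); general rotations
  permute sectors only approximately.
* No occlusion, propagation delay or sensor noise; no collision physics;
  single resource site is the tested configuration (multiple sites run but
  are unvalidated).
* Local (near-parent) offspring placement is deliberately not implemented:
  random placement is part of the model's design.
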