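---
title: "Modeling mitochondria-driven ROS propagation with rirrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mitochondria-driven ROS propagation with rirrsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rirrsim)
```

## The model

`rirrsim` simulates ROS-induced ROS release (RIRR) in a two-dimensional
cell. Every entity is a discrete agent on a continuous-coordinate pixel
grid (origin top-left, rectangles half-open):

* **Mitochondria** are axis-aligned 54 x 54 px squares arranged in one of
  five network layouts: a dense regular 9 x 9 lattice (the cardiomyocyte
  arrangement; 18 px vertical and 54 px horizontal gaps), a 5 x 5
  low-density lattice on the same 972 x 684 px cell, a uniformly random
  ("irregular") scatter, a center-clustered ("gradient", perinuclear)
  scatter, and a "moving" variant in which the outer ring of the lattice
  oscillates vertically as a triangle wave.
* **ROS agents** are superoxide (O2-) and hydrogen peroxide (H2O2).
  Each step every agent moves `speed * u` per axis, `u ~ Uniform(-0.5,
  0.5)` (maximum speeds 11.66 and 11.31 px/step), reflecting at the cell
  wall. Moves that change compartment (cytosol vs mitochondrion
  interior) survive only with a membrane-crossing probability; a
  rejected crossing cancels the whole move. H2O2 is membrane-permeant
  (0.5 per attempt in either direction); O2- is far less so (see the
  calibration section). Superoxide also decays spontaneously at 0.769%
  per step, H2O2 at 0.001% per step.
* **Antioxidant enzymes** (mitochondrial Mn-SOD and Gpx, cytosolic
  CuZn-SOD and Gpx) are slow-moving agents (1.414 px/step) confined to
  their home compartment. Their abundance follows the
  percent-of-whole-grid-pixels convention: `round(conc% x multiplier x
  grid pixels / 100)` agents (0.769, 0.914, 0.3 and 0.549 percent
  respectively), mitochondrial enzymes apportioned across mitochondria
  proportionally to area. When a substrate and an enzyme occupy the
  same integer pixel, the reaction fires with a per-encounter
  probability: SOD dismutates O2- to H2O2 in place with probability 1,
  Gpx removes H2O2 with probability 5e7 / 2.3e9 ~ 0.0217. Only the
  *ratio* of the two published rate constants is identifiable — the
  model has no physical time-step duration or pixel volume — so the
  faster reaction is saturated at 1 and the slower scaled by the ratio.
* **Respiration** generates superoxide: each mitochondrion undergoes
  `Poisson(0.01 x area)` respiration events per step, and each event
  leaks one O2- with the electron-leakage probability below. A
  mitochondrion holding strictly more than 50 O2- agents is classified
  **reactive**; the per-step fraction of reactive mitochondria is the
  model's main read-out.

An experiment starts from a quiescent cell plus an oxidative insult:
`initial_h2o2` H2O2 agents placed uniformly in a centered square
(default side 108 px, two mitochondrion lengths — the "restricted
center area" of the cell). Runs last `n_steps` (default 3000) and are
repeated over `n_replicates` (default 5) independent seeds
(`base_seed + 0, 1, ...`); results report mean and standard deviation
across replicates.

### The electron-leakage rule

The leak probability is a sigmoid in the mitochondrion's internal ROS
load, from a 1% baseline during normal respiration to 20% when the
mitochondrion is saturated with ROS:

* `as_printed`: `0.01 + 0.19 / (1 + exp(-wH*cH - wS*cS))` with weights
  `wH = 0.01`, `wS = 0.09`. At zero ROS this is 10.5%, which
  contradicts the 1% normal-respiration baseline; it is kept selectable
  for fidelity studies.
* `rescaled` (default): `0.01 + 2 * 0.19 * (plogis(wH*cH + wS*cS) - 1/2)`,
  the same sigmoid re-anchored so zero ROS gives exactly 1% while the
  saturation limit stays 20%.

**Units of the concentrations `cH`, `cS`.** Two interpretations ship.
`units = "agents"` feeds raw internal agent counts to the weights (the
literal printed form, and the default of the standalone
`leakage_probability()` calculator). The *engine* default is
`units = "percent_of_area"`: `c = 100 * n / area`, the mitochondrion-
local percent concentration. The choice is forced by a stability
analysis. With raw counts, a 54 x 54 mitochondrion respiring ~29
events/step has a rest-state feedback gain of about 7 — the derivative
of (events x leak probability) with respect to its own internal O2-
count, divided by the per-agent loss rate (~0.03/step from decay,
Mn-SOD encounters and membrane escape) — so every mitochondrion
amplifies its own baseline superoxide past the 50-agent reactive
threshold within ~100 steps with **zero** external stress, and no
admissible loss rate can fix this while leaving the threshold reachable
(rest stability would need losses > 0.25/step; reaching 50 agents under
saturated leakage needs losses < 0.12/step). With mito-local percent
units the rest gain is ~0.25: the resting load settles near 10 agents,
an oxidative insult raises the load past 50, and removing the insult
lets the cell relax. Percent-of-area units also make the rule
scale-free: a geometrically shrunken mitochondrion responds to the same
internal ROS *density*.

### Update order

The per-step order is fixed and documented for reproducibility:
mitochondrial motion, per-mitochondrion ROS tally, respiration,
diffusion of all species, membrane filtering, pixel reactions,
spontaneous decay, reactive classification. Event counters (leaks,
dismutations, Gpx removals, decays, injections) make the count
bookkeeping exact, and the test suite asserts it:
`n_O2- = leaked - dismutated - decayed` and
`n_H2O2 = injected + created - removed - decayed` at every endpoint.

## Analysis utilities

* `sweep_response()` runs replicate simulations across a dose or
  intervention-multiplier grid and records the final-step reactive
  fraction (mean, sd).
* `fit_polynomial()` / `rirr_threshold()` implement the dose-response
  regression: an unweighted least-squares polynomial (order 2 or 3),
  solved for the dose at which the fitted curve reaches 20% reactive
  mitochondria — the RIRR threshold. Root selection takes the smallest
  real root inside the sampled dose range; complex and out-of-range
  roots are discarded, and a curve that never reaches the target
  returns `valid = FALSE`.
* `messenger_lifetime()` combines a species' removal channels —
  spontaneous decay plus (enzyme occupied-pixel fraction x reaction
  probability), using the sparse occupancy approximation `n/pixels`
  (exact `1 - exp(-n/pixels)` selectable) — into a total per-step decay
  probability `p`, reporting the expected lifetime `N = 1/p` steps and
  the diffusive reach `sqrt(2 N L^2)` px with `L` the species' maximum
  speed. With spontaneous decay alone, O2- lives ~130 steps (reach
  ~188 px) while H2O2 lives 1e5 steps — the asymmetry that makes H2O2
  the long-range messenger. The `2NL^2` law is the mean-square
  displacement of the 2D fixed-step diagonal walk; the package contains
  a Monte-Carlo sampler of that walk (`simulate_diagonal_walk()`) used
  to validate the law, while the production sampler draws uniform step
  lengths (per-axis variance `speed^2/12`), a tension documented here
  rather than hidden. Lifetimes and reaches are reported in steps and
  pixels only: the model has no physical duration per step.

## Scaled study settings

Full-scale runs (81 mitochondria, 3000 steps, ~10k agents) take a few
minutes each; the package's own test suite and examples instead use
geometrically similar miniatures:

* `make_scaled_setting(factor = 3)`: a 324 x 228 px cell with 18 px
  mitochondria. Lengths, gaps, margin, injection side and **diffusion
  speeds** all divide by the factor, so a messenger's diffusive reach
  keeps its proportion to cell size and traversals take the same number
  of steps; the raw-count reactive threshold divides by `factor^2`
  (equal O2- density); per-step rates are scale-free and untouched.
* `make_mini_fixture()`: the fastest configuration (3 x 3 lattice of
  12 x 12 px mitochondria, 72 x 60 px cell, 200 steps, 2 replicates,
  dose 300 in a 24 px square), with the same speed and threshold
  scaling (12/54 and 144/2916). A replicate runs in well under a
  second.

Doses are agent counts; at equal H2O2 *density* a full-scale dose `D`
corresponds to `D x (area ratio)` in a scaled setting. The test suite
uses doses chosen so the scaled cell's response spans its dynamic range
(documented per test), and states its problem sizes (500-step runs,
5 replicates for the network-dependence checks) as the package's
choice of study scale.

What the miniatures preserve: compartment structure, the leak-rule
feedback (via percent-of-area units), enzyme occupancies, per-step
kinetics, reach-to-cell-size ratios. What they do not: agent-count
granularity (a 3 x 3 cell has 9 mitochondria, so reactive fractions
move in 11% steps) and any effect that needs thousands of agents per
compartment. Passing mini-scale tests therefore demonstrates the
mechanisms and their ordering, not the full-scale magnitudes.

## Membrane calibration

The model premise gives H2O2 high membrane permeability and O2- low
permeability, but no published values exist for the per-attempt
crossing probabilities; they are free parameters of this
implementation. The defaults were fixed once, before the assertion
suite was frozen, against three calibration criteria: (i) a resting
cell (dose 0) keeps its mean reactive fraction below 5% in every
layout; (ii) the dose response is monotone; (iii) inter-mitochondrial
O2- coupling is strong enough that antioxidant interventions
differentiate network layouts. H2O2 crosses at 0.5 per attempt in both
directions. For O2-, symmetric 0.05/0.05 crossing traps superoxide
inside its source mitochondrion and lets clustered layouts heat above
the rest bound, while 0.05 inward / 0.2 outward satisfies all three
criteria — and has a direct physiological reading: superoxide leaves
mitochondria through inner-membrane anion channels, the classical RIRR
release route, but re-enters poorly. Test margins for the
network-dependence checks were then set from pilot replicate variance
at these frozen defaults.

Enzyme loading follows the same calibrate-once logic. The published
concentrations are molarities, so the quantity held invariant across
layouts is per-compartment occupancy, scaled so the reference 9x9 cell
reproduces the published percent-of-grid values exactly (5113 Mn-SOD
agents, 0.769% of its pixels). Holding the *total count* invariant
instead would hand a 5x5 layout 3.24x the Mn-SOD occupancy per
mitochondrion and invert every density comparison.

## Synthetic data and realism

The model is itself synthetic: no external data enter. The layout
generators emulate network *geometry* only — real mitochondrial
networks undergo fission/fusion, size heterogeneity and curved
membranes, none of which are modeled. Enzyme kinetics are single-hit
per-pixel encounters without saturation (no Michaelis-Menten), there is
no hydroxyl radical, no catalase (no parameters for it exist), no
membrane-potential dynamics, and no conversion of steps to seconds.
Conclusions from this package are therefore about the agent-based
mechanism — network-dependent ROS propagation — not quantitative
biochemistry.

## Numerical choices

* Reflection at walls folds coordinates by mirror images and nudges the
  measure-zero landing on the far wall inside, preserving the half-open
  grid.
* Compartment queries use a cached pixel-resolution lookup table when
  every rectangle corner is integral (all built-in layouts; random
  placements snap to the pixel raster), falling back to a per-rectangle
  scan otherwise.
* Largest-remainder apportionment keeps enzyme totals exact under
  area-proportional allocation.
* Seeded rejection sampling places random layouts; placement failure
  after 1e5 attempts raises a capacity error rather than looping
  forever.
* Replicate `i` uses seed `base_seed + i - 1`; identical seeds give
  bit-identical runs.
* `rpois`/`rbinom`/`runif` from base R supply all randomness; there is
  one RNG stream per run.

## A worked mini example

```{r example, eval = FALSE}
fx <- make_mini_fixture(n_replicates = 3)
res <- run_replicates(fx$params, fx$geometry)
res

# dose-response and threshold at mini scale
curve <- sweep_response(fx$params, fx$geometry, "initial_H2O2",
                        c(0, 500, 1000, 2000, 4000))
rirr_threshold(curve, order = 3, target = 20)

# messenger kinetics under the default parameter set
messenger_lifetime("O2minus", sim_params())
messenger_lifetime("H2O2", sim_params())
```

## Known limitations

* The rest state is quiescent but not perfectly stationary: dismutated
  H2O2 accumulates slowly (its spontaneous decay is 1e-5/step and Gpx
  removal is slow), so very long unstressed runs drift warm. Catalase,
  which would cap the cytosolic H2O2 pool, has no published parameters
  and is not modeled.
* Per-mitochondrion feedback is monostable by construction (the
  logistic's steepest point sits at zero load), so whole-cell RIRR in
  this implementation is a graded, propagating response rather than a
  bistable switch; absolute reactive fractions depend on the chosen
  dose and horizon.
* The moving layout's amplitude (18 px, one vertical gap) and speed
  (1 px/step), the gradient layout's spread (`sigma = width/6`), and
  the injection square (108 px) quantify features the source material
  leaves qualitative.
* Three network-dependence orderings do not reproduce under this
  implementation's rules, and their test-suite assertions are left
  failing rather than weakened. (i) Mn-SOD protection is as steep in
  irregular as in regular networks: here Mn-SOD acts directly on every
  mitochondrion's internal O2- load, so protection tracks response
  amplitude in any layout. (ii) In the dense lattice, CuZn-SOD's edge
  over cytosolic Gpx is within replicate noise at miniature scale.
  (iii) The RIRR threshold is *lower*, not higher, for the dense
  network: a dense lattice simply places more mitochondria within the
  injected bolus's diffusive reach, and that geometric effect dominates
  the dense cell's larger total antioxidant sink at every dose. The
  passing counterparts (monotone Mn-SOD protection everywhere, the
  Gpx-over-CuZn-SOD reversal in sparse and irregular networks, dose
  monotonicity) are asserted with fixed seeds and pass
  deterministically.
```
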