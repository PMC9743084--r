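---
title: "Multiple-state transition path sampling and switching kinetics: methods"
author: "mstps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-state transition path sampling and switching kinetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(mstps)
```

## The problem

Conformational changes of biomolecules — the kind of rare barrier-crossing
events that separate metastable states of a protein — are poorly served by
plain simulation: the system spends almost all of its time inside stable
states and almost none on the transitions one wants to see.  Transition
path sampling (TPS) addresses this by running Monte Carlo *in trajectory
space*: starting from one reactive trajectory, it repeatedly perturbs and
regenerates parts of it, collecting an ensemble of unbiased reactive paths
without ever needing to know where the transition states are.

With more than two metastable states the natural generalisation is
multiple-state TPS (MSTPS): any pair of distinct states is an allowed pair
of path endpoints ("all-to-all"), and paths that leave a state only to
return to it (self-transitions) are excluded.  Because only one transition
(ordered state pair) is sampled at any Monte Carlo step, the sampler hops
— *switches* — between transitions over the course of the simulation, and
the pattern of those switches carries real information: frequent switching
between two transition channels indicates a flat, diffusive barrier region
connecting them, while absent switching indicates a high ridge.

This package implements the full protocol on a two-dimensional toy system
with known ground truth: the sampler (one-way shooting, flexible length,
all-to-all), the switch detection and kinetics solver, Monte-Carlo-weighted
path density histograms, and the convergence heuristics, plus the
synthetic generators used to validate every estimator against an
independent oracle.

## The toy system

The landscape is a sum of isotropic negative Gaussian wells,

$$ V(x) = \sum_k -d_k \exp\!\left(-\frac{|x - c_k|^2}{2 w_k^2}\right), $$

with depths $d_k$ in units of kT.  The bundled symmetric system
(`symmetric_three_well()`) places three wells of depth 4 kT and width 0.3
at the vertices of an equilateral triangle of circumradius 1; because the
wells barely overlap at this width, the barrier between any two wells is
within about 0.06 kT of the well depth.  Stable states are discs of radius
one well-width around the well centers — comfortably two thermal standard
deviations ($w\sqrt{kT/d} \approx 0.15$) — and are validated to be pairwise
disjoint at construction.  An asymmetric variant
(`asymmetric_three_well()`, one well at 2.5 kT) is bundled for
mechanism-difference demonstrations.

Dynamics are overdamped Langevin integrated with Euler–Maruyama at unit
mobility,

$$ x \leftarrow x - \nabla V\, \Delta t + \sqrt{2 D \Delta t}\; \xi, $$

with $\xi$ standard normal per axis.  By the Einstein relation the
diffusion coefficient plays the role of temperature ($D = kT$ at unit
mobility), so the stationary density is $\propto e^{-V/D}$ and at the
default $D = 1$ the well depths read directly in kT.  Setting $D = 0$
gives deterministic gradient descent, which several tests use as an
oracle.  The default timestep $\Delta t = 0.005$ keeps the stiffest
curvature of the bundled wells ($d/w^2 \approx 44$) well inside the
stability region ($\Delta t \cdot V'' \approx 0.22$).  The integrator
aborts with a diagnostic if a coordinate ever becomes non-finite.

Overdamped dynamics was chosen deliberately instead of a velocity-based
thermostatted integrator: one-way shooting only requires stochastic
dynamics whose time reversal is valid, which holds for reversible
diffusions, and dropping velocities removes all velocity-randomisation
bookkeeping from the shooting moves.

Two properties of this landscape matter for interpretation.  First, it is
*non-confining*: $V \to 0$ away from all wells, so the Boltzmann measure
over the whole plane is not normalisable and a free walker eventually
escapes to the flat region.  Transition *paths* are unaffected (they are
conditioned to end in states; non-terminating segments are rejected via
the length cap), but equilibrium occupancy statements only make sense
restricted to a region.  The test suite therefore checks the Boltzmann
shape of sampled positions *conditioned on a disc* around a well, and
checks equal-well occupancy on a variant with a broad symmetric confining
basin added underneath the triangle (which preserves the three-fold
symmetry exactly).  Second, Euler–Maruyama's stationary density deviates
from Boltzmann at $O(\Delta t \cdot V'')$; the Boltzmann-shape test uses a
reduced timestep so that this known discretisation bias stays an order of
magnitude below what the test could detect.

## The sampler

Each MSTPS trial:

1. chooses forward or backward with probability 1/2;
2. chooses a shooting frame uniformly over the current path's frames;
3. regenerates that side of the path with fresh dynamics — forward shots
   keep frames $1..k$ and integrate forward, backward shots integrate
   backward from the shooting frame (valid time reversal for overdamped
   dynamics) and keep $k..L$;
4. terminates the new segment as soon as a newly generated frame lies
   inside any state (the terminating frame becomes the path endpoint;
   frames are tested after each step, with no boundary interpolation);
5. accepts or rejects.

A trial is rejected outright if its endpoints do not lie in two distinct
states: self-transitions are excluded from the ensemble, and a segment
that exceeds the length cap without reaching any state is a rejection
(reason `"max_length"`), not an error.  Otherwise the trial is accepted
with probability

$$ p_{\mathrm{acc}} = \min\!\left(1, \frac{L_{\mathrm{old}}}{L_{\mathrm{new}}}\right), $$

where $L$ is the frame count.  This length ratio is the detailed-balance
correction required by uniform shooting-point selection in a
flexible-length ensemble: the proposal density into a path scales as
$1/L$, and the ratio restores balance.  The source publications of this
protocol do not generally state their flexible-length correction; this is
the standard choice and is documented here as such.

Remaining conventions, each genuinely open in the protocol and fixed here:

- **Shooting from an endpoint.**  Uniform selection includes endpoints.  A
  forward shot from the final frame generates at least one step of
  dynamics, but keeping that frame would place an in-state frame in the
  path interior, violating the ensemble definition; the assembled trial is
  therefore trimmed at its first in-state frame, so an endpoint shot
  yields a duplicate of the current path, which the acceptance rule
  handles like any trial.
- **Length cap.**  `max_length_factor = 50` times the initial path length.
- **Equilibration.**  With `equilibrate = TRUE` a pre-phase runs until the
  current path shares no frames with the initial path; the pre-phase is
  excluded from all production records, weights and residence times.
- **Frame identity.**  Every generated frame receives a fresh integer id
  from a monotone counter; retained frames keep their ids.  Identity, not
  geometry, defines decorrelation.
- **Randomness.**  One R Mersenne–Twister stream drives everything
  (the compiled kernels draw from R's RNG), so a single `seed` makes a
  whole run bitwise reproducible; runs are serial, so no per-trajectory
  child streams are needed.

Monte Carlo weight bookkeeping: every trial attributes one unit of weight
to the path that is current *after* the trial (an accepted trial starts
its path's count; each rejection extends the current path's count), and
the initial path carries one extra unit for its initial occupancy.  Hence
$\sum_i w_i = n_{\mathrm{trials}} + 1$ identically, which the code asserts
and the tests check on every run.

A *decorrelated* path is counted by a greedy scan: the initial path is the
first reference, and each later accepted path sharing zero frame ids with
the current reference becomes the next one.  Decorrelated paths are the
effectively independent draws from the ensemble; their count is the
headline measure of sampling quality, and they are the units on which the
statistically valid symmetry comparisons below are built.

## Switching kinetics

The per-trial label sequence (the transition of the current path after
each trial, so rejections extend residence) is reduced to count data: the
switch matrix $n_{ij}$ (number of switches from transition $i$ to $j$) and
the residence vector $t_i$ (MC trials spent sampling $i$), with the
identities $\sum_i t_i = N$, $\sum_{ij} n_{ij} = $ number of label
changes, $n_{ii} = 0$ asserted on every tally.

Assuming the switching itself samples an equilibrium distribution, the
population $P_i$ of transition $i$ satisfies the stationarity (global
balance) conditions built from the empirical per-trial switch rates
$\hat q_{ij} = n_{ij} / t_i$:

$$ \sum_{j \neq i} P_j\, \frac{n_{ji}}{t_j} \;=\; P_i \sum_{j \neq i} \frac{n_{ij}}{t_i},
\qquad \sum_i P_i = 1 , $$

a singular linear system closed by the normalisation constraint and solved
by least squares per connected component of the switch graph (components
are weighted by their share of total residence time, with a warning, when
the graph is disconnected; transitions never visited get $P_i = 0$ and are
flagged, never silently dropped).  From the populations, the switching
rate is

$$ k_{ij} = \frac{n_{ij}}{P_i\, N}, $$

the switch count divided by the effective residence time implied by the
equilibrium populations, reported per MC step and — the conventional
unit — per 100 MC steps (exactly $100\times$).  For a long equilibrium
chain $P_i N \to t_i$ and $k_{ij}$ converges to the Markov
maximum-likelihood estimator $n_{ij}/t_i$; the synthetic switch-chain
generator, whose true stationary vector is known analytically, is the
arbiter for both formulas, and the test suite verifies recovery of both
the stationary vector (total variation $< 0.02$ at $10^5$ trials) and the
generating probabilities (within standard errors) across seeds.

One combinatorial fact about one-way shooting deserves emphasis: a single
switch changes exactly one endpoint of the sampled transition (a forward
shot its final state, a backward shot its initial state), and endpoints
must remain distinct.  Breadth-first search over this move graph
(`min_switches_between`) shows that reversing a transition
(A→B to B→A) takes at least **three** switches for any number of states
$\geq 3$, and is impossible with only two states.  This is why healthy
MSTPS runs need to switch often: the forward and reverse versions of a
transition can only equilibrate through at least two intermediate
transitions.

Pooling independent chains sums counts and residence times before
solving.  A chain containing an *absorbing* transition — visited but never
switched out of — cannot contribute to an equilibrium estimate and is
excluded from the pool with a warning.

Analyses run in two modes, all accepted paths or decorrelated paths only
(`decorrelated_only = TRUE`); both are conventional and both appear in
reports.  Residence times exclude the equilibration pre-phase.

## Path density histograms

A path density histogram projects the path ensemble onto two collective
variables as a reactive flux: for each path, the set of bins visited by
*any* frame is computed, the path's MC weight is added **once** to each
visited bin no matter how often the path revisits it, and the grid is
divided by the total number of MC trials.  Each bin value is therefore the
fraction of sampling time during which the current path passed through
that bin, lies in $[0, 1]$, and — unlike a configurational density — is
not overwhelmed by long-lived intermediates.  Bins are half-open
$[\mathrm{lo}, \mathrm{hi})$ with the last bin closed; frames outside the
binning range are dropped and counted, never clamped.  The companion
per-frame histogram (`state_probability_histogram`), normalised to sum 1,
characterises the configurations a single state adopts within the
ensemble; endpoint frames are included by default, since trajectories stop
on arrival and endpoints are the only in-state frames a path ensemble
contains.

The implementation is tested for bitwise equality against an independent
brute-force implementation (per-path binary occupancy matrices, summed
with weights), and for the invariances that define the object: idempotence
under frame duplication, monotonicity under added paths, and linearity in
the weights before normalisation.

## Statistical design of the validation suite

Three choices in the test suite are worth recording because they are easy
to get wrong:

- **Autocorrelation.**  Consecutive accepted paths share frames and are
  strongly correlated, so naive binomial standard errors and naive
  two-sample KS tests on raw accepted-path statistics are anticonservative
  (sampler-vs-sampler control runs with independent seeds produce naive KS
  p-values down to $10^{-2}$ for identical distributions).
  Forward/backward count symmetry is therefore tested with a batch-means
  standard error (`path_count_symmetry`), and path-length distributions
  are compared on decorrelated paths (`decorrelated_length_ks`) or on
  systematic weighted subsamples spaced beyond the decorrelation time.
  The thresholds themselves (3σ, KS $p > 0.01$) are unchanged; only the
  units on which σ and $p$ are valid changed.
- **Familywise error.**  "Every rate within 3 standard errors" ranges over
  30 matrix entries (and several seeds); the familywise check uses the
  Šidák-style critical value at single-comparison 3σ strength
  ($\approx 3.9$ for 30 comparisons), which has the same 0.27% false-alarm
  rate as one 3σ comparison and unchanged power against an actually wrong
  estimator.
- **The ensemble oracle.**  The reference path-length distribution for the
  two-state micro-oracle is generated by the exact construction of the
  flexible-length ensemble: iid Boltzmann-distributed starting points
  inside state A (rejection sampling), conditioned to leave the state in
  one step, continued to first passage into any state, keeping the A→B
  connectors, under the same length cap as the sampler.  Shooting from a
  fixed "dividing point" instead conditions on a measure-zero event and is
  not the same ensemble.

Problem sizes were chosen once for statistical adequacy: $10^5$-trial
synthetic chains for estimator recovery, $10^4$ shooting trials for the
equilibrium-symmetry checks, 2000 trials (the standard production length
for this protocol) for the acceptance-ratio check, and $4 \times 10^5$-step
trajectories for the dynamics invariants.

## What the toy validation does and does not show

The synthetic modules emulate exactly two things: diffusive
barrier-crossing dynamics among ≥ 3 metastable states, and Markov
switching among transition labels with known rates.  Passing tests
therefore establish that the sampler targets the flexible-length
all-to-all ensemble it claims, and that the kinetics pipeline recovers
known switching dynamics from count data.  They do *not* establish
anything about force fields, solvent, collective-variable quality, or the
mechanism of any particular protein: real molecular systems have
high-dimensional, anisotropic, rugged landscapes for which the
two-dimensional Gaussian toy is only a topology-preserving cartoon.  The
collective-variable interface (arbitrary frame-to-scalar extractors in the
histogram functions, arbitrary label CSVs in the kinetics functions) is
the seam where real simulation data would plug in.

## Worked example

```{r example}
pot <- symmetric_three_well()
states <- three_well_states()
dyn <- dynamics_params()

chain <- run_mstps(pot, states, dyn, n_trials = 500, seed = 11,
                   equilibrate = TRUE)
summary(chain)

fit <- switch_kinetics(chain)
print(fit)
round(fit$rates$per_100_steps, 2)

path_count_symmetry(chain)
```

```{r figures, fig.show = "hold"}
plot(chain)
pd <- path_density(chain, breaks_x = seq(-2, 2, 0.1),
                   breaks_y = seq(-2, 2, 0.1))
plot(pd)
```

## Known limitations

- The per-trial label sequence attributes every rejected trial to the
  current transition; if a use case needs rejected self-transition trials
  attributed differently, the raw Monte Carlo record (`chain$records`)
  carries the full per-trial log.
- The population solver assumes the switching process is in equilibrium;
  for chains with an absorbing transition it refuses (by design) rather
  than extrapolating.
- Standard errors reported for switching rates are binomial; they ignore
  the (small, asymptotically vanishing) extra variance from estimating the
  populations.
- The dynamics kernel is specific to the 2D Gaussian-well family; the
  analysis layers (kinetics, densities, convergence) are
  representation-agnostic and consume label sequences and frame tables
  from any source.
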