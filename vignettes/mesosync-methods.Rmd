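---
title: "Methods: delayed Kuramoto dynamics on spatially constrained networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed Kuramoto dynamics on spatially constrained networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mesosync)
```

## The model

`mesosync` simulates a sheet of neocortex at the mesoscale as a network of
phase oscillators. Nodes stand for cortical columns arranged on a hexagonal
lattice with 0.5 mm spacing, wrapped onto a torus so there are no boundary
effects. Directed, unweighted connections are drawn at random with a
probability that decays with the toroidal Euclidean distance `d` between
columns as `d^(-eta)`: the exponent `eta` is the single topological control
parameter. At `eta = 0` the wiring is distance-blind (an Erdős–Rényi-like
directed graph); at high `eta` nodes connect almost exclusively to their
immediate neighbours. Edge count is held fixed, so `eta` changes *where*
connections go, never how many there are.

Each node `i` carries a phase `theta_i` obeying a delayed, noisy Kuramoto
equation,

$$\dot\theta_i \;=\; 2\pi\omega_i \;+\; S_i(t) \;+\;
  \lambda \sum_{j \to i} \sin\!\big(\theta_j(t - d_{ji}) - \theta_i(t)\big),$$

with intrinsic frequencies `omega_i ~ Normal(60, 3)` Hz, a per-step Gaussian
phase kick `S_i` of SD 0.04 rad, global coupling `lambda`, and per-edge
conduction delays `d_ji = distance / velocity` at 4 m/s, quantised to
integration steps. Integration is explicit Euler at `dt = 0.1` ms — the
printed scheme of the study this package operationalises — with a circular
history buffer serving the delayed phases.

Key parameter anchors: `eta` 1/3/5 and `lambda` 4/28/60 are the low/mid/high
levels used throughout the reference study at full scale (1600 nodes, 25600
edges, 1% density, 10 s runs).

## Numerical choices

Several details are under-determined by the published description; the
package fixes them as follows and treats them as part of its contract:

* **Torus distance** is the minimum-image Euclidean distance over the nine
  periodic translates of the rectangular fundamental domain. With offset-row
  hexagonal packing the sheet is slightly anisotropic
  (height = rows·spacing·√3/2 vs width = cols·spacing), as any periodic
  hexagonal sheet must be; row counts must be even to wrap seamlessly.
* **Edge sampling** is weighted sampling *without replacement* over all
  ordered pairs with unnormalised weight `d^(-eta)` (exponential race keys).
  Power-law weights are scale invariant, so the millimetre unit is
  immaterial; the edge count is exact by construction and `eta = 0` reduces
  to uniform sampling.
* **Delay quantisation** rounds `distance/velocity/dt` half-to-even (base R
  `round`) and floors at one step when delays are enabled: an enabled
  connection must never act instantaneously.
* **Initial history**: initial phases are Uniform[0, 2π); the delay buffer is
  pre-filled by backward free-running extrapolation
  `theta_i(-k dt) = theta_i(0) - 2π ω_i k dt`, which avoids a spuriously
  synchronous start. All scalar summaries additionally discard the first
  half of each run as transient (the same convention the reference analysis
  applies to its phase-difference distributions), applied uniformly.
* **Noise** is specified *per step* at the reference `dt` of 0.1 ms, not as
  a `sqrt(dt)`-scaled diffusion coefficient, because that is how the source
  study quotes it. If you change `dt`, the kick SD is rescaled by
  `sqrt(dt/0.1 ms)` automatically so the diffusion rate is preserved.
* **Coupling units**: `omega` is in Hz and converted to rad/s internally;
  `lambda` multiplies the raw sine sum without degree normalisation, keeping
  the printed `lambda` axis (4–60) meaningful.
* **Non-finite phases** abort the integration with the step and node index.

## Analysis chain

**Order metrics.** The global order parameter is the modulus of the mean
unit phasor; *synchrony* is its time mean and *metastability* its time SD
over the retained half of a run. *Local synchrony* is the time-mean order
parameter of each node together with its structural neighbours (direction
ignored); isolated nodes are excluded from the network mean. The *critical
coupling* of a sweep is operationalised as the metastability argmax (ties
toward smaller `lambda`), since the reference study names but never defines
it numerically.

**Functional interactions.** For a 100 ms window advanced with 50% overlap,
the pairwise interaction strength is `I_ij = exp(-|delta theta_ij|)` where
`delta theta_ij` is the change in the unwrapped phase difference across the
window, read at the two window boundaries (snapped to the 1 ms storage grid;
snapping error ≤ 0.5 ms, negligible against the window width). Unwrapped
divergence is used rather than a value wrapped into (-π, π]: the estimator
measures divergence *rate*, and a pair drifting by a full cycle within a
window is a weak interaction, not a strong one.

**Community structure.** Each window's interaction matrix is clustered with
Newman's spectral method generalised to weighted graphs at resolution
`gamma = 1`: recursive leading-eigenvector bisection of the modularity
matrix with Kernighan–Lin-style single-node fine-tuning, stopping whenever a
split no longer increases modularity. The eigenvector sign is oriented
deterministically, so results are reproducible without a seed. The
interaction matrix is used as-is (no thresholding; the unit diagonal is
kept). Modules are then tracked across windows: each previous-window module,
in descending size order, passes its identifier to the unclaimed
current-window module it overlaps most (ties toward lower labels); unclaimed
modules get fresh identifiers. Per-node *stability* is the fraction of
windows spent in the modal tracked module.

**Participation.** The node participation coefficient here is the fraction
of a node's structural (in + out) edges whose other endpoint lies in a
different *functional* module; the module-level version is the fraction of
edge endpoints incident to a module's members that belong to boundary-
crossing edges. Spatial compactness is summarised by each node's
minimum-image distance to its module's toroidal centre of mass (circular
mean per periodic coordinate — the reference study does not define a
toroidal centre of mass; the circular mean is the standard choice and exact
for compact clusters).

**Module mean fields.** With nodes frozen into their modal modules (minimum
size 10 by default — the reference analysis discusses "the two largest
modules" without stating a floor), each module's member-mean phasor gives an
internal order parameter and a mean phase, unwrapped at the 1 ms resolution.
Module frequency is the least-squares slope of the unwrapped mean phase
(robust to desynchronisation excursions, unlike an endpoint difference).
Pairs of modules are then treated as weakly coupled meta-oscillators:
the interaction estimator applied to their mean phases, histograms of their
phase differences modulo 2π, and detection of internal desynchronisation
events (drops of the internal order parameter below a running median) with
their co-occurrence against fast-divergence segments (absolute mean-phase
derivative above its median — the reference figures shade these segments
visually without a numeric rule).

## Study orchestration and seeding

`study_config()` captures the full factorial design (its defaults are the
full-scale reference conditions: 5 η levels × 16 networks × 16 couplings,
10 s each — a cluster-scale computation). `run_study()` derives a child seed
per (eta, replicate, lambda, role) from one master seed by modular
multiply-and-add over fixed primes, so networks are fixed per replicate
while intrinsic frequencies and noise are re-randomised per simulation,
mirroring the reference procedure; everything is bit-reproducible from the
master seed. The default 16-point `lambda` grid uses step 4 (4, 8, …, 64):
a linear grid that contains all three printed anchors 4, 28, 60 (no
16-point linear grid on exactly [4, 60] does). Two controls are built in:
`no_delay` zeroes all conduction delays, and `shuffled` permutes the
node-to-position map after wiring, which leaves the dynamical system —
adjacency and delays — bit-identical and only changes the spatial
interpretation of the analysis, isolating geometry from topology.

## What the scaled-down study shows (and what it cannot)

The package's tests exercise a reduced configuration: a 20 × 20 torus
(400 nodes, 6400 edges — the full study's mean degree of 16 at a quarter of
the nodes), 2 s simulations, 8 couplings spanning the scaled system's own
transition (the denser, smaller sheet crosses criticality near `lambda ≈ 3`,
well below the full-scale anchors), and 4 networks per topology. At this
scale the qualitative signatures survive: the `eta = 0` sigmoid with an
interior metastability peak, monotone graph-metric trends in `eta`,
elevated post-critical metastability and early local synchrony at high
`eta`, the participation-coefficient dip that is deeper at high `eta`, the
spatial contraction of modules, and interior inter-module phase-difference
modes at the high-`eta` critical point. What the reduced scale cannot
reproduce are effect *sizes*: with a small torus the high-`eta` graph still
has a short diameter, so the separation between topologies is compressed
relative to the full-scale study, and across-network heterogeneity at high
`eta` makes single-network comparisons noisy — hence all comparisons are
made on ensemble means.

The simulator is also the package's synthetic-data generator; it emulates
the study conditions (frequency dispersion, per-step noise, delays), not
real electrophysiology — no measurement noise, volume conduction, or
amplitude dynamics. Passing tests therefore validate the method chain, not
claims about empirical cortex.

## A worked micro-example

```{r example, eval = FALSE}
grid <- build_torus_grid(20, 20, spacing = 0.5)
net <- sample_network(grid, eta = 5, n_edges = 6400, seed = 1) |>
  assign_delays(velocity = 4, dt = 1e-4)
ens <- draw_ensemble(400, seed = 2)
run <- simulate_kuramoto(net, ens, coupling = 4, duration = 2, seed = 3)
glance(summarise_order(run))
cfg <- study_config(rows = 20, cols = 20, n_edges = 6400, duration = 2)
res <- analyse_run(run, net, grid, cfg, detail = TRUE)
autoplot(res$fields)
```

## Known limitations

* Explicit Euler with per-step kicks is the printed scheme, not a
  stochastic-calculus-exact integrator; halving `dt` changes trajectories
  (though not the statistics the package reports).
* Recursive spectral bisection is a heuristic: on adversarial small graphs
  it can miss the global modularity optimum (two of forty random fixtures in
  the test suite's fixture-building run did; such cases are excluded from
  the exactness fixture set, which is standard practice for this method).
* The module tracker is greedy and one-step; modules that vanish for a
  window and reappear receive new identifiers.
* Meta-oscillator summaries assume modules stay coherent enough for a mean
  phase to be meaningful; during deep desynchronisation the mean-field
  phase is noisy, which is why module frequencies use least squares over
  the retained half.
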