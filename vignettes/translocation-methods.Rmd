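---
title: "Model and methods: driven polymer translocation through an attractive nanopore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: driven polymer translocation through an attractive nanopore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poretrans)
```

## The physical model

`poretrans` simulates a coarse-grained polymer pulled through a narrow
cylindrical pore in a membrane, the standard computational cartoon of
voltage- or motor-driven DNA/RNA translocation experiments. The chain is a
bead–spring polymer of $N$ identical monomers of diameter $\sigma$ and mass
$m$:

* **Excluded volume** between *all* bead pairs (bonded neighbours included)
  is the WCA potential — a Lennard-Jones potential truncated at its minimum
  $2^{1/6}\sigma$ and shifted up by $\epsilon$, so it is purely repulsive:
  $U_{\mathrm{WCA}}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] +
  \epsilon$ for $r \le 2^{1/6}\sigma$, zero beyond.
* **Connectivity** comes from FENE springs between adjacent beads,
  $U_{\mathrm{FENE}}(r) = -\tfrac12 k R_0^2 \ln(1 - r^2/R_0^2)$, with
  $k = 30\,\epsilon_0/\sigma^2$ and $R_0 = 1.5\sigma$. Combined with the
  bonded WCA term the bond minimum sits near $0.96\sigma$
  (`equilibrium_bond_length()` solves for it exactly).
* **The membrane** is two laterally infinite walls pierced by a cylinder of
  length $6\sigma$ and radius $R_p \in \{1.5, 2, 2.5, 3\}\sigma$ (pore
  diameters $3\sigma$–$6\sigma$). All membrane parts are *continuous
  surfaces*: a bead interacts through the Euclidean distance from its
  centre to the surface. Walls repel beads through the same WCA form;
  the inner pore surface attracts them through a full Lennard-Jones
  potential cut at $2.5\sigma$ with well depth $\epsilon_{\mathrm{pore}}$
  — the central control parameter, studied over
  $\{0.1, 1, \dots, 8\}\,\epsilon_0$.
* **The drive** is a constant force $f\hat{x}$ applied only to beads whose
  centre is currently inside the pore, with $f = 1$ (medium) or $2$
  (strong) $\epsilon_0/\sigma$. `force_regime_bounds()` gives the regime
  boundaries $k_BT/(\sigma N^\nu) \le f \le k_BT/\sigma$; the Flory
  exponent defaults to $\nu = 0.588$, the 3D self-avoiding-walk value
  consistent with the excluded-volume chain.

Dynamics follow the Langevin equation
$m\ddot{\vec r}_i = \vec F^C_i - \xi \vec V_i + \vec F^R_i$ with friction
$\xi = 0.7\,m/t_{LJ}$ and thermal energy $k_BT = 1.2\,\epsilon_0$.

### Units

Internally everything is in reduced Lennard-Jones units
($\sigma = \epsilon_0 = m = 1$, so $t_{LJ} = \sqrt{m\sigma^2/\epsilon_0}
= 1$). Mapping to DNA — Kuhn length $\sigma = 1.5$ nm, bead mass
$936$ amu, $T = 295$ K — fixes $\epsilon_0 = k_BT/1.2 \approx 3.39\times
10^{-21}$ J and $t_{LJ} \approx 32.1$ ps:

```{r units}
p <- simulation_parameters()
epsilon0_joules(p)
lj_time_unit(p)   # picoseconds
```

## Numerical choices

**Integrator.** The update rule is a BBK-type Langevin velocity Verlet:
one Gaussian random force per bead, component and step with variance
$2\xi k_BT/\Delta t$ (the white-noise discretisation demanded by the
fluctuation–dissipation theorem), applied in both half-kicks, and the
friction of the second half-kick treated semi-implicitly. Three exact
properties make it testable: with $\xi = 0$ and no noise it reduces to
deterministic velocity Verlet (energy drift below $10^{-4}\epsilon_0$ over
$10^5$ steps in the suite); the free-particle damping factor per step,
$(1-a)/(1+a)$ with $a = \xi\Delta t/2m$, matches $e^{-\xi\Delta t/m}$ to
third order; and the stationary free-particle velocity variance is
*exactly* $k_BT/m$ at any $\Delta t$, so the kinetic temperature check is
limited only by Monte Carlo error.

**Timestep.** $\Delta t = 0.005\,t_{LJ}$ by default, capped at $0.01$: the
combined FENE+WCA bond has curvature $\approx 900\,\epsilon_0/\sigma^2$
near its minimum, and larger steps destabilise it. Halving $\Delta t$
changes desk-scale mean translocation times by less than their standard
error (checked in the suite).

**Cutoff dialect.** The attractive pore potential written in the
plus-$\epsilon$ form jumps by $\approx 0.984\epsilon$ at its $2.5\sigma$
cutoff. The simulator defaults to the truncated-and-shifted form
(`pore_dialect = "shifted"`), which is continuous at the cutoff and changes
the well depth by under 2%; the literal form remains selectable because
forces — hence trajectories — are identical in both dialects, only energy
book-keeping differs.

**Membrane distances.** Wall distance is the minimum over the two annular
faces; where the perpendicular foot would land inside the aperture the
distance is taken to the rim circle, giving a continuous (1-Lipschitz)
field around the pore mouth — a discontinuous repulsion at the rim would
destabilise the integrator. Inside the bore the walls are inactive (the
inner cylinder takes over). On the axis the lateral gradient of these
axisymmetric fields is set to zero (the symmetric limit of the cone
singularity). Pair forces use a direct $O(N^2)$ loop: at $N = 50$ neighbour
lists would cost more than they save.

**Degenerate inputs.** Bead–bead or bead–surface contact below
$10^{-9}\sigma$ and FENE extension $r \ge R_0$ abort the step with the bead
indices; the event driver records such attempts as `numerics_failed` and
re-runs them on a fresh random substream.

## Protocol

The initial configuration threads the chain: bead 1 on the axis exactly at
the trans exit plane, successive beads laid back through the pore at the
equilibrium bond length, the cis tail given a small deterministic helical
offset ($0.1\sigma$) to break collinearity. Beads initially inside the pore
(plus bead 1) are pinned while the tail equilibrates under full
thermostatted dynamics without the drive. Convergence is declared when the
range of the tail's radius of gyration falls below $2\sigma$ over a
window of 200 samples taken every 50 steps; the $2\sigma$ threshold is part
of the protocol, the cadence (a $50\,t_{LJ}$ window) is the package's
choice. Velocities are then resampled from the Maxwell distribution, all
beads released, and the pull switched on.

During the driven phase a monotone first-passage counter records, for every
$s = 1\ldots N$, the first time $s$ beads simultaneously sit past the trans
exit plane; re-entries never erase a recorded time, and times of later
monomers can never precede earlier ones. An event ends `completed` when
$s = N$; if every bead retreats past the cis plane it is `retracted`,
discarded, and re-run on a fresh substream (the count of discards is kept —
only successful passages enter the statistics). Every event is seeded from
`(base_seed, stream)` so single events are reproducible in isolation and
ensembles are order-independent.

## Observables

* **Cumulative mean exit time** $\langle t(s)\rangle$ and **waiting time**
  $w(s) = \langle t(s+1)\rangle - \langle t(s)\rangle$; the two telescope
  exactly, which the suite asserts to machine precision.
* **Crossing point**: the first $s$ at which the cumulative curve at one
  pore attraction crosses that at another (`crossing_index()`, ties count
  as crossings).
* **Centre of mass** $X_{COM}(s)$, and the two shape descriptors evaluated
  on configurations snapshotted at each first-passage instant:
  **aspect ratio** $\alpha = \Delta x / (2\sqrt{y_{max}^2 + z_{max}^2})$
  over trans-side beads (axial protrusion over lateral spread, both
  measured from the pore axis/exit plane), and **shape factor**
  $\delta = R_g/R_h$ over *all* beads, with $R_h$ the Kirkwood estimate
  $R_h^{-1} = N^{-2}\sum_{i\ne j} r_{ij}^{-1}$. The anchor scale runs from
  $\sqrt{3/5} \approx 0.77$ (gyration over geometric radius of a uniform
  ball — `delta_sphere_anchor()`) to $4.0$ for a rod. The Kirkwood
  estimator is one defensible bead-level closure of "compare gyration and
  hydrodynamic radius"; it is isolated behind `shape_factor_delta()` so it
  can be swapped, and on a dense uniform ball it evaluates to
  $\approx 0.93$ — near, but not equal to, the geometric anchor. The
  printed anchors are treated as scale ends, not assertions about this
  estimator.

## What the default conditions emulate — and what they do not

The defaults *are* the studied conditions: $N = 50$, $k_BT = 1.2$,
$\xi = 0.7$, pore length $6\sigma$, the four radii, the nine-value
attraction grid $\{0.1, 1, 2, \dots, 8\}$ (the grid ends and count are
stated; the interior spacing is the natural reading), the two forces, pore
centre $(40, 38, 40)$. Production scale is $\ge 1500$ events per condition
(`sweep_plan(preset = "production")`); the test suite and the acceptance script
run 25 and 200 events per condition respectively, sizes chosen so the
whole suite completes on one CPU in about a minute of simulation per
condition while still resolving the ordinal effects.

A passing suite therefore shows that the *model* reproduces the qualitative
physics — slower translocation through stickier and narrower pores,
bell-shaped waiting times, early-$s$ acceleration and late-$s$ retention
under strong attraction, ascending final waiting times at
$\epsilon = 8, R_p = 1.5\sigma$ — under this integrator and these
replicate counts. It does not validate quantitative agreement with any
particular experiment, and real polymers add sequence heterogeneity,
hydrodynamic interactions, electrostatics and solvent structure that this
coarse-grained model deliberately omits.

## Known limitations

* **Unstated discretisation of the reference results.** The integration
  scheme and timestep behind the published curves are unknown, so per-$s$
  magnitudes differ in detail. In this implementation the
  cumulative-curve crossing between $\epsilon = 8$ and $\epsilon = 1$ at
  $R_p = 1.5\sigma, f = 2$ sits near $s \approx 20$–$24$ (200 events);
  the ordinal structure (strong attraction ahead early, behind late) is
  robust.
* **Adsorption-dominated corner of the grid.** With a wide bore and the
  strongest attraction ($R_p = 2.5$–$3\sigma$, $\epsilon = 8$) the
  continuous-surface well binds beads by several $\epsilon_0$ per bead
  against $k_BT = 1.2$, and single events stretch to
  $\sim 2\times 10^4\,t_{LJ}$ — hundreds of times slower than
  $\epsilon = 1$. These conditions are supported but not desk-scale; the
  shipped analyses use the narrow pore for the strong-attraction contrast.
* **Open lateral boundaries.** Walls are laterally infinite and space is
  open (no periodic box): the membrane is the only static obstacle, which
  is adequate for a single $N = 50$ chain but not for dense multi-chain
  systems.
* **Retraction handling.** Retracted events are discarded and redrawn,
  matching statistics over successful passages only; unbiased ($f = 0$)
  translocation statistics are out of scope.
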