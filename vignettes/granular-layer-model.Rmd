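---
title: "Reconstructing and simulating the cerebellar granular layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and simulating the cerebellar granular layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The granular layer is the input stage of the cerebellar cortex: mossy
fibers (MFs) excite granule cells (GRCs) and Golgi cells (GOCs) inside
synaptic glomeruli (GLOs); GRC axons ascend and branch into parallel
fibers that excite GOC apical dendrites, and GOC axons inhibit GRCs back
inside the glomeruli, closing feedforward and feedback inhibitory loops.
`granlayer` rebuilds this circuit in a parametric 3D volume and simulates
its activity with conductance-based neuron models and kinetic receptor
synapses. This vignette documents the model, every tunable parameter that
matters, the numerical choices, and the design decisions taken where the
underlying anatomy or physiology does not pin down an implementation.

## 1. The design stage

### Element counts and placement

A configuration (`network_config()`) fixes the volume (default 600 um
along x, 150 um height, 1200 um depth), per-class densities (9,000 GOC,
4,000,000 GRC and 300,000 GLO per mm^3 — rat values) and soma diameters
(15 / 5 / 5 um). Counts are `floor(density * volume)`: the reference
volume hosts 972 GOCs, 432,000 GRCs and 32,400 GLOs.

Placement is boxed: the height is cut into layers sized by the soma
diameter of the class being placed, each layer is a grid of square-based
boxes (side = diameter), and a box hosts at most one element. Placing an
element fixes x and y at the box center and draws z uniformly inside the
box; with the default dimensions the box height equals the diameter, so z
degenerates to the box mid-height. GOCs go first on their own 15 um grid;
GLOs and then GRCs share one 5 um grid (which by construction prevents
same-class and GLO-GRC overlaps) under the additional constraint that
their somata must not intersect any GOC soma (center distance >= sum of
radii). Each element draws random boxes until it fits, up to
`placement_retry = 200` attempts, after which it is recorded as skipped —
partial placement is valid output, not an error. At the reference scale
and occupancies, essentially all elements place (the granule grid is
filled to ~54%), comfortably above the 98% level the test suite demands.

Placement draws are batched: all pending elements of a class draw boxes
simultaneously, collisions (occupied box, duplicate draw, GOC overlap)
reject the losers, and the survivors retry in the next round. This is
statistically equivalent to per-element retries, deterministic under the
seed, and fast enough to place the full 432,000-granule volume in about a
second.

### Connection matrices

Six matrices encode the circuit; all caps and geometric rules are
configuration parameters.

* **`link_grc_glo`** — every GRC sends up to 4 dendrites to *distinct*
  GLOs within 40 um (mean dendrite length 13.6 um is reported but the
  hard constraint is the 40 um reach); a GLO accepts at most 50
  dendrites. Because total demand (432k x 4) exceeds total capacity
  (32.4k x 50), the assignment is computed by random-priority proposal
  matching: every in-reach GRC-GLO pair gets an i.i.d. priority, GRCs
  propose their best-priority candidates, GLOs accept up to spare
  capacity, and rounds repeat until no proposal lands. Per GRC only the
  24 best-priority candidates are retained (`max_candidates`), which
  bounds memory at full scale; with ~80 GLOs in reach of a typical GRC
  this leaves the outcome statistics unchanged. At full scale ~82% of
  GRCs obtain all 4 dendrites and ~97% of GLOs fill their 50 slots.
* **`link_goca_glo`** — a GOC axon inhibits at most 40 GLOs inside an
  axonal field modeled as an axis-aligned box centered on the soma
  (default 650 x 80 x 80 um, elongated along x because Golgi axons spread
  longitudinally; the anatomy gives no numeric field, so the extents are
  configurable). Candidates are visited in random order and accepted only
  if they share no granule cell with the GLOs already chosen, so no GRC
  is inhibited twice by the same GOC.
* **`link_gocdb_glo`** — basal dendrites sample up to 40 GLOs at random
  from a disk of radius 80 um in the soma's horizontal plane, within half
  a box height vertically; this realizes the ~40 MF inputs per GOC.
* **`aa_goc_link` / `pf_goc_link`** — around each GOC an elliptical
  cylinder bounds the apical-dendrite field (major axis 150 um along x,
  minor 50 um along y, both configurable; the anatomical sketch is a
  trapezoid, the ellipse is our smooth stand-in). 400 ascending-axon
  inputs are sampled uniformly from the GRCs inside the ellipse but
  outside a small exclusion cylinder under the soma (radius = 2 x GOC
  radius) where contacts are unlikely. Parallel fibers run along the
  depth axis, so any GRC whose (x, z) track crosses the field can
  contact it: 400 local contacts are drawn from inside the ellipse and
  1,200 distal ones from outside. The literature also quotes a 1,000:1
  PF:GOC convergence; we implement the explicit 400 + 1,200 split and
  expose both quotas as parameters.
* **`gap_junction`** — GOCs couple electrically to their up-to-2 nearest
  neighbors within 100 um (configurable), formed greedily in ascending
  distance order so the matrix is symmetric; border cells may end with 1
  or 0 partners.
* **`mf_glom_clustering`** — see below.

### Mossy-fiber rosette clustering

Each MF branches into a spatially compact cluster of rosettes, one
rosette per glomerulus, with 7.7 +/- 4.1 rosettes per cluster and every
member within 350 um of the cluster mean. We therefore partition the
GLOs into `n_clusters` balanced clusters of size 8 +/- 4 (target and
half-width configurable). The default cluster count is
`floor(n_glo / 8)` = 4,050 at reference scale; analyses that fix 4,051
MFs treat that number as configuration input. Centroids initialize on
randomly chosen GLO positions; each GLO is assigned to its nearest
centroid and its 100 nearest centroids are stored sorted by distance.
Over-full clusters (size > 12) shed their farthest members, each moving
preferentially to a K-nearest under-full cluster (< 4), otherwise to the
nearest cluster below `target + delta/2` = 10, otherwise below 12, never
beyond 350 um. A final pass pulls the nearest spare members into
clusters still below 4. At full scale all clusters land in [4, 12] with
maximum member-centroid distances around 150 um.

### Determinism and tie-breaking

All randomness flows through R's RNG seeded once from `config$seed`;
stages consume the stream in a documented fixed order (placement,
granule dendrites, Golgi axons, basal dendrites, AA/PF, gap junctions,
clustering), so identical configurations give bit-identical networks.
Ties (equal distances, equal priorities) resolve to the lowest id.

## 2. The neuron models

Both cell classes are single-compartment Hodgkin-Huxley models. The
membrane obeys

$$C_m \frac{dV_m}{dt} = -(I_{ions} + I_{syn} + I_{gap}) + I_{ext},$$

each ionic current is `I = g (Vm - E)` with
`g = gbar * x^z * y^k`, and every gating particle follows
`dn/dt = alpha(V)(1 - n) - beta(V) n`, advanced with the exact
exponential update `n(t+dt) = n_inf - (n_inf - n) exp(-dt/tau)` where
`n_inf = alpha/(alpha+beta)` and `tau = 1/(alpha+beta)`. Rate laws are
stored in the parameter files as functional forms (exponential, sigmoid,
linoid, calcium-dependent binding) plus coefficients, with per-channel
Q10 temperature factors (default 30 degrees C).

The granule cell carries fast, persistent and resurgent Na currents,
delayed-rectifier, A-type, inward-rectifier, calcium-dependent and slow
K currents, an HVA Ca current and leak; sodium and potassium reversal
potentials are constant while the calcium reversal is recomputed every
step from the Nernst equation, fed by a submembrane calcium shell

$$\frac{d[Ca]}{dt} = -\frac{I_{Ca}}{2FAd} - \beta_{Ca}([Ca]-[Ca]_0)$$

(area `A`, depth `d` = 0.2 um, clamped at zero). The Golgi cell adds the
h current, LVA Ca, and an SK-type K-AHP channel modeled as a six-state
Markov scheme (four closed states chained by calcium-binding steps, two
open states), advanced by first-order Euler of the master equation
written as pairwise fluxes and renormalized.

**Parameter provenance.** The kinetic coefficients and densities are not
part of the circuit description itself; they are shipped as editable
JSON files (`inst/extdata/grc_soma.json`, `goc_soma.json`) written from
the canonical granule-cell model lineage (D'Angelo et al. 2001) and
Golgi pacemaker lineage (Solinas et al. 2007), and then *calibrated* so
the cells reproduce the documented phenotypes: the granule cell rests
near -79 mV and is silent without input; the Golgi cell pacemakes
regularly at ~10 Hz with zero input (ISI CV ~0.03); a granule cell
driven on all four dendrites by a 100 Hz mossy-fiber burst fires only
after 3-4 stimuli. Any analysis that depends on these files is
parameter-sensitive in the same sense: replacing the files changes the
cellular behavior without touching the network code.

## 3. The synapse models

The presynaptic terminal is a three-state release scheme
(recovered/active/inactive, the Tsodyks-Markram form): a spike moves a
fraction `u = 0.43` of the recovered pool into the active state, which
inactivates with `tau_in` = 3 ms and recovers with `tau_rec` = 35 ms,
producing use-dependent depression. Transmitter `T` is emitted as a
rectangular pulse (1 mM for 0.3 ms) while a release event is active, and
is zero otherwise — the simplest form consistent with pulse-like
cleft transmitter.

Receptors are kinetic schemes of first-order reactions whose binding
rates scale linearly with `T`: AMPA with 3 states (C/O/D), NMDA with 5
(C1/C2/C3/O/D) and GABA-A with 8
(C/CA1/CA2/OA1/OA2/DA1/DA2/DA2f) in two variants, alpha1 and alpha6,
summed per inhibitory contact. Peak conductances are fixed at 1,200 pS
(AMPA), 18,800 pS (NMDA) and 918 / 132 pS (GABA alpha1/alpha6). The
NMDA current is multiplied by the standard voltage-dependent magnesium
block `B(Vm) = 1/(1 + exp(-0.062 Vm) [Mg]/3.57)` with `[Mg]` = 1 mM
(configurable); the block form is our choice — only its existence, not
its formula, is anatomically prescribed. The total synaptic current is
exactly `I_syn = I_NMDA + I_AMPA + I_GABA`. Rate constants, like the
channel coefficients, are shipped parameter files adapted from the
granular-layer synapse model lineage (Nieus et al. 2006, 2014) and
calibrated to realistic EPSC/IPSC time courses and to the 3-4-stimulus
integration behavior above.

Each granule cell owns four excitatory and four inhibitory synapse
objects, one pair per dendrite/glomerulus; each Golgi cell owns one
pooled synapse per buffer (basal excitatory, apical excitatory,
inhibitory). Whether real granule dendrites carry pooled or separate
conductances per glomerulus is not settled; one synapse per buffer
matches the four-buffer bookkeeping of the simulation loop.

## 4. The simulation engine

The network loop advances in fixed steps of `dt` = 0.025 ms. Per step:

1. due MF spikes fan out through their rosette cluster to every
   connected granule dendrite buffer and Golgi basal buffer (delay
   `delay_mf`, default 0.5 ms);
2. every GOC consumes its due buffer spikes, advances its synapses,
   channels, Markov scheme, calcium and membrane potential (including
   the gap current computed at the end of the *previous* step), and on
   spiking enqueues deliveries to the inhibitory buffers of every
   granule dendrite reached through its axonal glomeruli
   (`delay_goc` = 0.5 ms);
3. gap currents `I_i = sum_j g_gap (V_i - V_j)` (default
   `g_gap` = 0.2 nS, configurable — no value is prescribed) are
   recomputed from the fresh GOC potentials, to be consumed next step;
   they start at zero because all cells start at the same potential;
4. every GRC does the same and enqueues spikes to the apical buffers of
   its GOC targets with the ascending-axon (0.5 ms) or parallel-fiber
   (1.0 ms) delay.

Because every delay is at least one step, a spike can never be consumed
in its emission step, and the evaluation order within a population is
immaterial: identical inputs give bit-identical rasters. Spike detection
is an upward crossing of -20 mV with a 1 ms minimum interval (the
detection rule is ours; only the spikes themselves are physiologic).

Numerics: gating uses the exact exponential update with `n_inf` and
`tau` recomputed each step; membrane potential, calcium, Markov and
receptor schemes use first-order Euler, with all master-equation fluxes
evaluated on the pre-update occupancies so total occupancy is conserved
to machine precision. In the compiled engine the voltage-dependent
`n_inf` and `exp(-dt/tau)` are precomputed on a 0.02 mV grid over
[-120, 80] mV and linearly interpolated; calcium-dependent rates are
always evaluated analytically. The tables change spike times by well
under a millisecond on the fixture; an analytic mode
(`use_tables = FALSE`) reproduces the pure-R single-cell stepper to
float precision and is used by the cross-check tests. Synapses at rest
(no release in flight, occupancy back in the unbound state) are skipped,
which is exact, not approximate.

Background MF trains are periodic at the protocol rate starting at
`delta` = 350 ms — this reproduces the published input accounting
(about 4,050 spikes per second over 4,051 fibers) deterministically;
burst onsets are drawn uniformly per bursting fiber and snapped to the
step grid. The four standard protocols are: Prot1, 1 Hz background on
every MF; Prot2, 100 Hz/50 ms bursts on 10% of MFs; Prot3, background
plus a burst on every MF (a stress test); Prot4, background plus bursts
on 1% of MFs.

## 5. Analysis utilities

`connection_stats()` reports the design-quality summaries (glomerulus
slot occupancy, granule dendrite counts, basal/axonal quota fill, gap
junction degrees, cluster size and distance distributions).
`estimate_memory()` evaluates the closed-form byte counts of the three
stages — design: `600 + 15432 n_goc + 32 n_grc + 1292 n_glo + 296 n_mf`;
CPU simulation: `42542 n_goc + 12220 n_grc + 204 n_glo + 8004 n_mf`;
GPU simulation: `580 + 2788 n_goc + 7172 n_grc` — and
`max_gpu_volume()` inverts the last for a given device RAM. Reported
MB/GB use binary units (MiB/GiB), because the published ~2.88 GB figure
for the reference counts (3,101,014,516 bytes) matches only the binary
reading; decimal values are printed alongside. `run_center_surround()`
drives the MFs whose cluster centroid falls in a 50 um disk with a
150 Hz/50 ms burst and bins granule firing rates on the x-y plane,
reproducing the excited-core / inhibited-surround organization.

## 6. Problem sizes, what the tests show, and limitations

The test suite exercises the full-scale *design* stage (placement over
20 seeds, quotas, clustering: all fast) but simulates *activity* on a
reduced 150 x 150 x 150 um fixture — 30 GOCs, 13,500 GRCs, 1,012 GLOs,
126 MFs, about 14.5k cells — for 1 s of spontaneous activity and ~0.35 s
of center-surround stimulation. These sizes are the package's chosen
desk-scale working points; the engine itself is size-agnostic and the
design stage is validated at full scale.

What passing tests do and do not show: the generator produces networks
whose *statistics* (placement fractions, quota fill, cluster-size
distributions) match the reported full-scale figures, and cells whose
*phenotypes* (silence, pacemaking, burst integration) match the
documented behaviors. They do not show that the shipped channel and
receptor coefficients equal the original published tables — those values
are transcribed-and-calibrated, as flagged above — nor that the
emergent population dynamics quantitatively match in vivo recordings.
Real granular layers also feature dendritic morphology, stochastic
channel gating, spillover and short-term plasticity beyond the
desensitized states, all outside scope. Multi-compartment morphologies
and the molecular/Purkinje layers are natural extensions the design
stage already leaves room for.
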