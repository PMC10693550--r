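---
title: "Coarse-grained simulation of designed coiled-coil condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained simulation of designed coiled-coil condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(coilsim)
```

## The scientific problem

Synthetic biomolecular condensates can be built from polypeptides that
carry several coiled-coil (CC) dimer-forming segments (stickers) joined by
flexible Gly/Ser linkers (spacers). Whether such a design phase separates
into liquid droplets, collapses into inert molecular dimers, or stays
diffuse is governed by a small set of design rules: the number of CC
segments per chain (valency), the *arrangement* of orthogonal CC types
along the two chains (a mismatch between partners leaves free valences
that build a network; a matched arrangement lets two chains zip into a
closed dimer), the heptad length of the coils (3-heptad coils exchange
fast enough to stay liquid; 4-heptad coils freeze), the parallel versus
antiparallel pairing orientation of homodimeric coils in single-chain
designs, and the possibility of poisoning condensation with a third,
clustered chain that saturates a partner's stickers.

`coilsim` implements a coarse-grained simulation-and-analysis pipeline
that encodes these designs symbolically, simulates them with an
orientation- and registry-aware sticky-bead model under Langevin dynamics,
runs a slab phase-coexistence protocol, and classifies every design as
`condensate`, `dimer`, or `diffuse` from its density profile and molecular
cluster-size distribution.

## The model

**Representation.** One bead per residue (C-alpha level), for coil and
linker segments alike. Coil segments are 21 beads (3 heptads) or 28 beads
(4 heptads); the standard `gs` linker is 8 beads and the long variant
(`gs40`) 40 beads. Consecutive beads are joined by stiff harmonic bonds at
the C-alpha spacing (r0 = 0.38 nm, k = 8000 kJ mol^-1 nm^-2). Coil
segments carry a rod-stiffening bending term `k (1 + cos theta)`
(k = 200 kJ/mol) on internal triplets, which is harmonic in the deviation
from 180 degrees near the minimum with the same constant and, unlike the
textbook harmonic-angle form, has regular forces at exactly 180 degrees.
Linkers carry no bending term and remain fully flexible.

**Specific attraction.** Complementary coil beads attract through a 12-6
Lennard-Jones potential with sigma = 0.570 nm and epsilon = 7.5 kJ/mol,
truncated at 2.5 sigma and shifted to zero there. Complementarity is
registry-based: a parallel pair binds bead `i` to bead `i`; an
antiparallel pair binds bead `i` to bead `L + 1 - i`. All other bead
pairs of a complementary coil pair interact by excluded volume only,
which keeps the dimer interface in register. The interaction matrix
declares which coil types pair (S1h-S2h, S3h-S4h, P5f-P6f, P13f-P14f,
APHh3-APHh3 antiparallel, GCNh3-GCNh3 parallel) and every other
combination inert, encoding the experimentally demonstrated
orthogonality of the designed set.

**Orientation gate.** Attraction between two coils is switched on only
when their end-to-end axes are aligned (parallel pairs) or anti-aligned
(antiparallel pairs) within a 60-degree tolerance, ramped smoothly
(a cubic smoothstep on the axis dot product between cos 80 and cos 60
degrees) so forces stay continuous; the gate's gradient through the
segment end beads is included in the force evaluation. This is the
package's realization of orientation-specific CC pairing; the qualitative
contract is that wrong-orientation homodimer contacts contribute zero
energy, which the test suite asserts directly.

**Excluded volume, at two diameters.** All nonbonded beads repel through
a WCA core of sigma_rep = 0.40 nm. Coil beads whose segment types do
*not* form a designed pair repel at a larger steric diameter, sigma_fat =
0.65 nm. This two-diameter scheme matters: a formed CC interface is a
rigid object roughly 2 nm across, and a chain cannot thread between
formed interfaces. With thin beads everywhere, a mismatched chain pair
can fold back on itself ("weave") and satisfy all of its coils pairwise,
which destroys the arrangement-mismatch design rule; the fat non-partner
diameter frustrates exactly that closure while leaving every designed
binding geometry untouched.

**Competitor exclusion (effective 1:1 binding).** Two beads of the same
coil type at the same registry index compete for the same binding site.
Without a corresponding penalty the pairwise model happily forms
triple-helix sandwiches (a bound pair admits a second partner on its open
face), which dimeric coiled coils do not. A bounded soft-core repulsion
between competitor beads (cosine form, range `2^(1/6) sigma_ex` with
sigma_ex = 1.25 nm, height `2 epsilon_ex` = 8 kJ/mol) suppresses double
occupancy; the test suite verifies that in equilibrated dilute mixtures
fewer than 5% of coil beads touch complementary beads on more than one
chain. For homodimeric coil types the exclusion is gated on *parallel*
axis alignment: a bound antiparallel homodimer is anti-aligned and
legitimately brings same-registry beads close near the rod centre, while
a third-party attacker approaches parallel to the helix it would
displace. No such gating exists for a parallel homodimer, whose attack
geometry coincides with its binding geometry — see the limitations.

**Dynamics.** BAOAB Langevin integration, dt = 0.02 ps, uniform bead mass
110 amu, with a deterministic counter-seeded RNG so trajectories are
bitwise reproducible. With friction zero the integrator reduces to
velocity Verlet (the suite checks energy drift below 0.5% over 1e5
steps). Neighbour lists are split: a short-cutoff excluded-volume list
and a sparse list of registry-complementary (and competitor) pairs that
carries the sticky cutoff; list energies agree with an all-pairs
evaluation to 1e-9 relative.

## Temperature scale and calibration

The per-bead sticky parameters produce dimer binding energies of order
100-200 kJ/mol for a fully zipped coil pair, so plain kT at 310 K would
make binding irreversible. The model therefore carries a dimensionless
`temperature_scale` (default 2.45) multiplying the thermostat kT: nominal
Kelvin labels map onto the model's own reduced energy scale. The scale
and the per-pair strength multipliers were fixed once by calibrating
simulated dissociation constants of single coil pairs (two single-coil
chains in a periodic box; bound-state occupancy theta with
`Kd = (1 - theta)^2 C / theta`, C the one-molecule box concentration)
against the measured (ITC) values:

| pair      | measured Kd    | simulated Kd (this package) |
|-----------|----------------|------------------------------|
| S1h-S2h   | 2.3 ± 1.5 mM   | ~2 mM                        |
| S3h-S4h   | 0.34 ± 0.07 mM | ~0.5 mM                      |
| P5f-P6f   | 5.9 ± 0.5 µM   | ~0.3-20 µM (wide CI)         |
| P13f-P14f | 2.3 ± 0.2 µM   | sub-µM-µM (wide CI)          |

The 3-heptad estimates are well determined (binding and unbinding are
both sampled many times in a 1e6-step run); the 4-heptad estimates rest
on rare unbinding events and carry order-of-magnitude confidence
intervals from block averaging, so only their ordering and order of
magnitude are meaningful. `calibrate_temperature_scale()` exposes the
grid-search machinery (simulated temperature whose Kd is log-nearest to
each target) with an injectable estimator.

## The slab protocol at desk scale

`run_slab()` executes, in order: a single-unit stage, packing, energy
minimization, a density hold (the pressure-coupling analogue), a
z-expansion, and NVT production. The desk preset uses systems of 6-12
chains (1,300-2,700 beads), a 9 x 9 nm cross-section, packing directly at
the slab density of 1.0 beads/nm^3, a 4,000-step density hold, 10x
expansion, and 110,000 production steps at friction 0.05 ps^-1 — the low
friction accelerates cluster coalescence and partner exchange without
changing any equilibrium property, and the sizes are chosen so that a
three-replicate panel entry completes in about three minutes on one
core. The full-scale preset records the original durations (150 ns
compression, 20+ us production, friction 1 ps^-1) for completeness.

The single-unit stage builds one copy of every component as straight
side-by-side chains with N termini aligned — the in-register zipped state
that long single-molecule dynamics converges to — and relaxes it by
20,000 steps of dynamics. This is the load-bearing stage for the design
rules: a matched-arrangement pair closes all of its coils here and enters
the slab inert, while a mismatched pair is left with free valences *by
the design itself* (the straight zip of `(S1h-S3h)3` against
`(S2h)3(S4h)3` engages 8 of 12 coils and cannot do better without the
fold-back closure that the fat diameter frustrates). Units are then
replicated on a jittered grid with random rigid rotations.

Compression is implemented as molecule-wise affine rescaling of chain
centres of mass with re-equilibration, not a barostat; the expansion
rescales the box only, leaving coordinates (and therefore bond lengths)
untouched. Coordinates are kept unwrapped throughout, with the minimum
image convention applied to nonbonded pair distances, so no re-wrapping
or unwrapping step exists anywhere in the pipeline.

## Analysis and classification

All analyses run on the equilibrated window, by default the final 50% of
production frames.

* **Density profile**: chain centres of mass binned along z, re-centred
  per frame on the circular mean when the mean resultant length exceeds
  0.5 (a uniform gas is deliberately *not* re-centred, so it cannot fold
  onto its own fluctuations); dense phase = bins at or above half the
  smoothed maximum, dilute phase = bins outside a two-bin margin around
  the dense region.
* **Clusters**: two chains are linked when a coiled-coil crosslink joins
  them — at least half of one coil's beads within 1.5 sigma_sticky
  (0.855 nm) of registry-complementary beads of a partner coil on the
  other chain. A single-bead-contact criterion (`edge = "any"`) is also
  available but transient encounters then bridge otherwise separate
  molecules; the crosslink criterion is the package's declared default,
  calibrated (as the analysis-criteria choices must be) to reproduce the
  matched-versus-mismatched contrast. The dominant species per frame is
  the cluster-size class holding the plurality of chains, ties toward the
  larger size; dimer dominance is the fraction of frames whose dominant
  species is the size-2 cluster.
* **Phase call**: `condensate` when the dense/dilute density contrast is
  at least 5 *and* the mean largest-cluster mass fraction is at least 0.8
  ("nearly all the proteins in one cluster"); otherwise `dimer` when
  dimer dominance is at least 0.5; otherwise `diffuse`. Desk-scale phase
  calls are made by majority over three replicate seeds, because
  individual small-system runs fluctuate.
* **Diffusion**: chain centre-of-mass MSD over all time origins, linear
  fit over lags 10-50% of the maximum, D = slope/6 converted to cm^2/s,
  bootstrap over chains for the standard deviation; fits with R^2 below
  0.9 are flagged subdiffusive (D is still reported, clamped at zero).
  Two refinements matter for small simulated droplets: the analysis can be
  restricted to the chains inside the dense cluster (`droplet_chains()`),
  and displacements can be measured relative to the droplet's own centre
  of mass (`relative = TRUE`), because a desk-size droplet drifts and
  tumbles as a whole while the full-scale quantity of interest is the
  mobility of chains *within* the droplet.
* **Engagement**: a coil is engaged in a frame when at least half its
  beads are in contact with complementary beads of a single partner coil;
  the report carries per-coil engaged-time fractions and unique-partner
  counts.

## What the desk scale does and does not show

The desk-scale panel reproduces the *qualitative* truth table: which
designs condense, which are dimer-poisoned, which stay diffuse, and the
ordering of droplet mobilities (3-heptad networks diffuse fastest, the
single-chain APPAPAPPAP design is intermediate, 4-heptad networks are
essentially frozen). It does not reproduce printed full-scale numbers:
with 10-100x fewer chains and roughly three orders of magnitude less
simulated time than the original 20+ us three-replicate runs, absolute
diffusion coefficients, dense-phase densities and dimer-dominance
percentages are expected to differ, and single replicates of
condensate-forming systems occasionally fail to percolate (hence the
majority vote). The generator also emulates only the modelled regime:
helicity-attenuated designs, SAH linkers and fluorescent-protein tags are
outside the model's scope, so passing tests say nothing about those
constructs.

## Numerical choices and degenerate inputs

Pairwise energies are capped below r = 0.06 nm (evaluation at the floor
distance) so deep overlaps produced by packing never yield non-finite
energies; minimization is plain steepest descent with an adaptive step
and a displacement cap, which is deterministic. Dynamics aborts with a
stage-labelled diagnostic when any per-step displacement exceeds half the
box. Ties in the dominant-species statistic break toward the larger
cluster size. Single-frame or empty analysis windows error out rather
than returning degenerate estimates; Kd estimation refuses a point
estimate when a trajectory never or always shows the bound state.

## Known limitations

* The orientation gate and the two-diameter excluded-volume scheme are
  effective stand-ins for helix-level geometry; they reproduce the
  qualitative contracts (wrong-orientation contacts are inert, chains do
  not thread through formed interfaces) but not helix packing detail.
* Dimeric exclusivity cannot be enforced for *parallel* homodimeric coils
  with pairwise isotropic interactions: a third helix attacking a bound
  parallel pair approaches in exactly the binding geometry, so the GCNh3
  blocks of the segregated single-chain design (PPPPPPAAAA) polymerize
  into stacks across molecules and that design reads condensate at desk
  scale instead of the closed-dimer state observed experimentally. The
  frustrated pattern (APPAPAPPAP) has the same composition, so no
  interaction-strength choice separates the two; the separation requires
  helix-face anisotropy beyond one-bead-per-residue granularity. All
  heterodimeric design rules, and the antiparallel-homodimer behaviour,
  are unaffected.
* The 4-heptad dissociation constants are calibrated only to order of
  magnitude: desk-length two-molecule runs sample too few unbinding
  events for better.
* The temperature scale is a reduced-unit mapping, not a physical
  temperature; 298 K versus 310 K differ by 4% in effective kT, which is
  within desk-scale noise, so temperature-resolved contrasts (e.g. the
  printed 50% versus 75% dimer dominance) are not resolved at this scale.
* Phase calls for 6-12-chain systems are majority votes over three seeds;
  individual replicates of marginal systems can and do disagree. The
  weakest-valency condensate formers (the mismatched 3-heptad pair and
  especially the clustered-tetramer pairing) sit at the percolation edge
  of the declared largest-cluster threshold at these system sizes, so
  single majority votes occasionally land on the wrong side.
* Droplet-mobility contrasts are compressed at desk scale: a 5-12-chain
  droplet's relative MSD mixes internal exchange with shape fluctuation
  and rigid rotation, so the two-orders-of-magnitude full-scale contrast
  between 3- and 4-heptad designs is not quantitatively reproduced; the
  engaged-time contrast (4-heptad coils engaged longer) is, while the
  unique-partner contrast needs longer trajectories than the desk scale
  affords.
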