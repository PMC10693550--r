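# coilsim

Coarse-grained simulation and analysis of designed coiled-coil (CC)
condensates.

Synthetic membraneless condensates can be engineered from polypeptides
that carry several CC dimer-forming segments (stickers) joined by short
flexible linkers (spacers). Whether a design phase separates, collapses
into inert molecular dimers, or stays diffuse is set by a handful of
design rules — sticker valency, the arrangement (mismatch) of orthogonal
CC types between partner chains, coil heptad length, parallel versus
antiparallel pairing orientation, and the possibility of poisoning
condensation with a third clustered chain. `coilsim` implements the full
simulation pipeline that tests these rules in silico:

* **constructs** — a symbolic grammar for multi-coil polypeptides
  (`"Cit-(S1h-S3h)3-gs"`, `"APPAPAPPAP-gs"`), expanded to one-bead-per-residue
  chains with per-bead coil registries;
* **force field** — registry- and orientation-specific sticky beads
  (12-6, sigma = 0.570 nm, epsilon = 7.5 kJ/mol per complementary bead
  pair; parallel pairs bind registry `i` to `i`, antiparallel `i` to
  `L+1-i`), WCA excluded volume with a larger steric diameter between
  non-partner coils, a competitor-exclusion term that keeps CC interfaces
  one-to-one, harmonic bonds and rod-stiffening bending terms;
* **engine** — BAOAB Langevin dynamics with split Verlet lists, energy
  minimization, and box operations, in compiled code with a deterministic
  seeded RNG;
* **slab** — the phase-coexistence workflow (single-unit relaxation,
  packing, density hold, 10x expansion, NVT production) plus dimer-Kd
  estimation and temperature-scale calibration against measured (ITC)
  affinities;
* **analysis** — density profiles, molecular cluster-size distributions,
  phase classification (`condensate` / `dimer` / `diffuse`), MSD-based
  diffusion with bootstrap errors, and coil-engagement statistics, all
  returned as tibbles with `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Classify the matched-arrangement two-chain design — the pair whose chains
zip into closed, LLPS-incompetent molecular dimers instead of condensing:

```r
library(coilsim)

panel <- design_panel()
entry <- panel[panel$id == "matched_3h", ]    # (S1h-S3h)3 + (S2h-S4h)3
sys <- panel_system(entry, seed = 1)
slab <- run_slab(sys, slab_protocol(), seeds = 1:3)
calls <- analyze_slab(slab)
calls
#> <cc_phase_summary> majority label: dimer (dimer, dimer, dimer)
tidy(calls)[, 1:5]
#> # A tibble: 3 x 5
#>   replicate label density_contrast largest_cluster_fraction dimer_dominance
#>       <int> <chr>            <dbl>                    <dbl>           <dbl>
#> 1         1 dimer            240                      0.167            1
#> 2         2 dimer             41.2                    0.362            0.83
#> 3         3 dimer            216.                     0.212            1
```

The three evidence columns are the markers used throughout: the
dense/dilute density contrast along the slab axis, the mean fraction of
chains in the largest molecular cluster ("nearly all" chains in one
cluster for a condensate), and the fraction of equilibrated frames in
which size-2 clusters are the dominant species — the signature of dimer
poisoning, near one here because every chain pair has zipped closed. The
arrangement-mismatched partner entry (`"mismatch_3h"`), identical in coil
content but alternating versus clustered, forms a percolating network
under the same protocol instead; at the desk scale its majority call sits
near the declared largest-cluster threshold and can land on either side
for a given seed triple (see the limitations section of the methods
vignette).

Single-pair dimer affinities, the quantity the temperature scale is
calibrated against:

```r
estimate_dimer_kd(c("S1h", "S2h"))[, c("pair", "theta", "kd_molar", "flag")]
#> # A tibble: 1 x 4
#>   pair    theta kd_molar flag
#>   <chr>   <dbl>    <dbl> <chr>
#> 1 S1h:S2h 0.321  0.00138 ok
```

(1.4 mM, against 2.3 +/- 1.5 mM measured by ITC for this pair.)

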