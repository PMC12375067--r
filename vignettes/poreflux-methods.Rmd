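---
title: "Analyzing ion permeation through channel pores with poreflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing ion permeation through channel pores with poreflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflux)
```

## The problem

Non-selective cation channels such as the cyclic-nucleotide-gated CNGA1
channel conduct both K⁺ and Na⁺ through a short selectivity filter (the
T362–E365 stretch in CNGA1 numbering) and a hydrophobic central-cavity gate
(F389/V393).  Molecular-dynamics simulations of such channels under a
transmembrane voltage produce microsecond trajectories from which one wants,
reproducibly:

* **permeation events** — complete traversals of the pore, with direction
  and entry pathway (on-axis versus through an off-axis "side pocket"
  behind the filter);
* **conductance** — net transported charge per time and voltage, with a
  segment-based uncertainty;
* **occupancy** — volume-normalized 1D/2D ion density along the pore and
  mean simultaneous ion counts in the filter and pore (the knock-on
  bookkeeping);
* **hydration** — how many water versus protein oxygens coordinate the ion
  as it crosses the narrow filter (partial dehydration);
* **pore geometry** — inscribed-sphere radius profiles, gate distances,
  gate water counts, and their block-averaged correlation;
* the accompanying **statistics** — unpaired Student's *t* tests with the
  conventional significance labels, and kernel density estimates.

poreflux implements this pipeline for R, together with a synthetic
trajectory generator that carries its own ground truth, so every stage can
be validated at desk scale without any MD output.

## Coordinate frame and units

All internal lengths are nm, times ps, energies kT at 300 K.  The pore axis
is box *z* through the centroid of a reference selection
(`define_pore_axis()`), with **+z toward the extracellular side**; a
principal-axis mode exists for tilted pores.  The sign convention is
recorded in every file the package writes.  PDB input (Å) is converted at
the I/O edge; GRO/DCD/JSON trajectories keep nm.

Periodic boundaries are handled in two places.  `unwrap_axial()` makes each
ion's z-series continuous (jumps larger than half the box height are
corrected by a whole box length); `detect_events()` applies the same
correction internally to the series it extracts, so it accepts wrapped or
unwrapped input and the correction is idempotent.  Distances for hydration
shells and pocket spheres use the minimum-image convention, tested against
an explicit 27-image enumeration.

## Permeation events

The pore interval `[z_lower, z_upper]` splits the axis into
ABOVE / INSIDE / BELOW.  Per ion, an event is recorded when a traversal that
entered INSIDE through one boundary exits through the other; re-exit through
the entry boundary cancels the pending traversal, and excursions inside that
never reach a boundary are ignored.  Because bulk above and below are
connected through the periodic box, the pore interval is *tiled* along the
unwrapped axis: an ion that permeates, wraps, and permeates again produces
one event per traversal, and the net event count per ion equals its net
number of box-spanning displacements.

Two timing conventions matter:

* `t_enter` is the first frame observed inside the pore (for the rare
  traversal with no interior frame, the last frame on the entry side);
  `t_exit` is the first frame beyond the far boundary.  Dwell time is their
  difference, reported in ns.
* Crossings are resolved at frame resolution, with no sub-frame
  interpolation; the event count is stable under subsampling until the
  frame interval approaches the fastest boundary-to-boundary passage
  (property-tested on synthetic data).

The boundary values are not universal constants: for real trajectories they
should be anchored to the structure (≈0.2 nm beyond the E365 carboxylate
oxygens and the F389 Cα, respectively), and every output echoes the values
used.  For synthetic runs `boundaries_from_spec()` mirrors the generator's
ground-truth boundaries.

An event is classified `side_pocket` when the ion was inside any configured
pocket sphere within `pathway_memory` (default 200 ps, the order of
binding-site residence times in synthetic tests) before its first entry
into the filter window; both the fraction among completed traversals and
the fraction among all filter-entry episodes are reported, since the two
denominators answer different questions.

## Voltage and conductance

An applied uniform field gives `V = E · Lz` (reported in mV).  For
charge-imbalance (dual-bathtub) setups the transmembrane voltage is obtained
by integrating the one-dimensional Poisson equation
`d²V/dz² = −ρ(z)/ε₀` twice from the lower box face and differencing the two
bulk plateaus; the implementation reproduces the parallel-plate closed form
`ΔV = σd/ε₀` within 1% at 0.01-nm bins.

Conductance converts net event counts: `g = n·e / (t·|V|)` in pS with
`e = 1.602176634×10⁻¹⁹ C` exactly.  Counts are direction-resolved ("net")
by default — at |V| ≥ 100 mV opposed crossings are rare — with a gross
counter available.  Each run is cut into segments (default 100 ns) by event
*completion* time; the leading segment(s) of each run are discarded as
equilibration, and the mean ± SD is pooled over all retained segments of
all runs, so five 1-µs runs with one discarded segment each yield exactly
45 analysis segments.  Segments without events legitimately contribute zero
conductance.  `instantaneous_conductance()` applies the same conversion in
consecutive 20-ns windows, and `iv_curve()` assembles I(V) = g·V with the
standard error of the segment mean propagated.

## Occupancy maps and knock-on bookkeeping

`occupancy_1d()` counts ion-frames in z-bins inside a radial cutoff and
divides by frames and cylindrical bin volume, giving mean ions/nm³ per
frame (an exact conversion factor to the ions-per-0.001-Å³ convention is
documented).  `occupancy_2d()` uses annular (z, r) bins normalized by
`2π·r_mid·Δr·Δz`, which equals the exact annulus volume at mid-point radius,
so an azimuthally uniform distribution appears flat in r.  Every emitted
map satisfies the conservation identity
`Σ density × bin_volume = mean in-region ion count` to 1 part in 10¹⁰, and
marginalizing the 2D map over r reproduces the 1D counts bin-for-bin.
Defaults Δz = 0.05 nm, Δr = 0.025 nm, radial cutoff 1.2 nm.

`site_occupancy()` reports mean simultaneous ion counts in the named filter
regions (S_intra/S_central/S_extra, default ±0.15 nm windows around the
generator's well centers or, for real input, around the coordinating
atoms), the whole filter, the pore, and the side pocket, with SD across
runs.  Several ions simultaneously in the filter is the knock-on signature;
a species with deeper filter wells shows higher mean occupancy, which the
suite verifies as a sign-recovery test.

## Hydration shells

The first shell is all oxygens within a species-specific radius of the ion:
0.31 nm for Na⁺ and 0.34 nm for K⁺, the first minimum of the ion–oxygen
pair distribution.  The boundary is closed (an oxygen exactly at the radius
counts) — the direction of that convention is arbitrary but fixed and
documented.  "Protein oxygens" means every oxygen in a protein residue,
backbone or side chain.  `hydration_profile()` assigns each (ion, frame)
observation to the z-bin of the ion and reports per-bin mean water, protein
and total oxygen counts (total = water + protein exactly, by construction)
with SD across runs; observations outside the binned range are counted and
warned about, never silently dropped.

## Pore geometry

`pore_radius_profile()` computes, at each z, the radius of the largest
sphere centered in that plane that touches no atom's van der Waals surface:
`radius(z) = max_c min_a (|c − a| − vdw(a))`, solved by Nelder-Mead from
five starts (previous slice's center plus four jittered starts, tolerance
10⁻⁴ nm well inside the reported precision).  A Bondi-style radius table is
built in; a custom table can be supplied to match other radius sets.
Slices with no candidate atoms, or where the optimizer escapes the
structure (radius beyond a cap set by the lateral box size), are flagged as
gaps rather than fabricated.  Correctness is established on analytic
scaffolds (`ideal_geometry()`): rings placed at target-plus-vdW radius make
the true accessible profile known exactly, and the profiler recovers
cylinder and hourglass targets within 2% with the waist located to one
sample spacing.

`gate_metrics()` reports both declared diagonal gate distances (opposing
pairs are honored as declared, never re-derived as nearest neighbors),
their minimum, and the water-oxygen count in the gate region — default a
±0.4 nm z-slab around the gate atoms with a 0.6 nm radial cutoff, since the
gate region has no universal definition.  `block_correlation()` reduces two
series to non-overlapping block means (default 20 ns) before the Pearson
correlation, suppressing autocorrelation; the incomplete trailing block is
dropped and at least three blocks are required.

## Statistics

`students_t_unpaired()` is the classic pooled-variance two-tailed test
(df = n₁+n₂−2), with Welch's form available as a sensitivity flag; labels
follow the conventional thresholds ns (p > 0.05), * (≤ 0.05), ** (≤ 0.01),
*** (≤ 0.001), applied exactly.  p-values are cross-checked against a
permutation oracle in the suite.  `kde_distribution()` evaluates a
Gaussian-kernel estimate with Scott's-rule bandwidth on an explicit grid
(default: data ± 3 bandwidths) and renormalizes to unit trapezoidal mass —
the 3-bandwidth grid clips ≈0.27% of each kernel's tail, so without
renormalization the unit-mass contract could not hold.

## The synthetic generator and what it does (not) emulate

`simulate_channel()` propagates ions with the overdamped Langevin update

```
x(t+Δt) = x(t) + D·f(x)·Δt + sqrt(2·D·Δt)·η,    f = force/kT
```

with axial forces from three Gaussian binding wells (S_intra, S_central,
S_extra), a uniform field `q·E/kT`, and screened-Coulomb pair repulsion
`U/kT = A·exp(−d/λ)/d` (A ≈ the 0.7 nm Bjerrum length, λ = 0.8 nm — the
minimal mechanism that produces knock-on without solvent); lateral forces
from a harmonic wall outside a pore-radius function and an off-axis 3D
Gaussian side pocket.  Idealized waters diffuse freely inside the wall and
do not interact with ions — hydration operations are validated with planted
scenes (`plant_hydration_scene()`), not emergent solvation.  Noise comes
from one seeded generator with per-particle streams at fixed offsets, so
runs are bit-reproducible and adding particles does not reshuffle earlier
ones.

Defaults are chosen as desk-scale study conditions: a 6×6×12 nm box with 40
ions per species (≈150 mM in that volume), wells at z = 1.05/1.40/1.75 nm
(widths 0.12 nm), K⁺ wells 2.5 kT and Na⁺ wells 3.5 kT deep (Na⁺ binds the
filter more strongly, reproducing the sign of the occupancy and dwell-time
contrasts), diffusion coefficients 1.96×10⁻³ (K⁺) and 1.33×10⁻³ nm²/ps
(Na⁺), a 0.5 ps timestep (rejected as unstable if the drift displacement
per step exceeds half a well width), and a field giving +100 mV across the
box.  The generator records ground truth at integration-step resolution: a
traversal log with entry pathway flags and the true unwrapped axial path of
every ion.

What passing synthetic tests shows: the bookkeeping — event detection,
segmentation, normalization, shell counting, profiling, statistics — is
correct on data whose truth is known.  What it does not show: force-field
realism.  The generator has no explicit solvent, no protein flexibility, no
electrostatics beyond the pair term and uniform field, and makes no attempt
to reproduce the real channel's conductance magnitudes.

## Numerical choices and problem sizes

* χ² Boltzmann checks save frames every 4 ns — beyond the periodic-box
  diffusion relaxation time L²/(4π²D) ≈ 1.9 ns — because χ² needs
  approximately independent samples; bins are 0.5 nm with expected counts
  well above 5.
* The oracle-equivalence check runs 50 seeded trajectories of 200 ions ×
  10⁵ frames against an independently written per-frame state machine;
  sign-recovery runs 10 replicates of 20+20 ions × 10⁵ steps.  These sizes
  keep the full suite in the tens of minutes on one CPU while leaving the
  statistical checks well-powered.
* Ties and degenerate inputs: zero pooled variance, all-identical KDE
  samples, empty event lists, single-atom "channels" and boundaries outside
  the box all raise typed errors or warnings rather than silently
  degrading; pending traversals at trajectory end are discarded.

## Known limitations

* XTC/TRR readers are not available in this R environment; the package
  reads GRO/PDB topologies with DCD or its JSON dialect trajectories, and
  the dialect is the native format of the synthetic generator.
* The HOLE-style profiler reproduces the inscribed-sphere definition with a
  multistart local optimizer, not HOLE's simulated-annealing schedule;
  agreement is established on analytic geometries, and a HOLE radius file
  can be supplied when matching HOLE output on real structures.
* Whether published side-pocket percentages count filter entries or
  completed permeations is ambiguous; both counters are exposed.
* Conductance uses net (direction-resolved) counts by default; the gross
  counter is provided because either convention may be needed to match a
  given report.
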