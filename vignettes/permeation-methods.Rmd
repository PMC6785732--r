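---
title: "Methods: ion permeation analysis for Kir channel trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion permeation analysis for Kir channel trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeon)
```

## The analysis problem

Inwardly rectifying potassium channels (Kir; the G-protein-gated GIRK2 /
Kir3.2 in particular) conduct K⁺ through a long pore with three
constrictions stacked along the membrane normal: the cytoplasmic G-loop
gate (G318/M319), the hydrophobic helix-bundle-crossing (HBC) gate
(F192), and the selectivity filter (SF) with its five canonical binding
sites S4 (intracellular) to S0 (extracellular). In simulations under an
applied field, both gates flicker and wet/dewet on the nanosecond scale
while ions pass in single file — so naive analyses (counting plane
crossings, averaging distances over all frames) mislead. `permeon`
packages the analyses that handle this correctly, and a synthetic data
generator whose ground truth makes each analysis falsifiable.

All coordinates are in Ångström, times in picoseconds, energies in
kcal/mol; the pore axis is +z by convention (an `axis_direction` flag
mirrors landmark comparisons for −z-oriented systems rather than
transforming coordinates). Converters for nm/kJ inputs are provided.

## Committed-crossing event detection

A permeation event on an interval `[z_lo, z_hi]` is recorded only when
the ion's unwrapped z trace passes from below `z_lo − m` to above
`z_hi + m` without first returning behind the plane it came from
(`detect_events()`); the committed margin `m` defaults to 2 Å. Flicker —
arbitrarily many recrossings of a gate plane with amplitude below the
margin — therefore produces zero events, which the
`flicker_no_crossing` scripted scenario asserts. The rule is applied to
every periodic image of the interval, so an ion that permeates, wraps
through the periodic boundary and permeates again is counted once per
passage. Ion traces are unwrapped with a minimum-image rule on
successive frames (jump threshold half the box height): permeation
counting presumes continuous traces.

The full-SF interval runs from the lower S4 boundary to the upper S0
boundary; HBC and G-loop events are committed crossings of a single
landmark plane. The margin choice matters only between 0 (flicker
recounting) and roughly half the inter-landmark spacing (events
swallowed); 2 Å sits comfortably in that plateau and the suite checks
stride-halving robustness at this value.

Rates are per-run counts over simulated time; group summaries use the
sample standard deviation (n−1), which reproduces the reference table's
printed 10.8 exactly. Conductance is `g = N·e/(t·V)` with the exact SI
elementary charge, reported in pS.

## Effective-biased PMF by Boltzmann inversion

`occupancy_profile()` counts ions in 0.5-Å slices between the
intracellular entrance and the SF end, inside a radial cutoff (8 Å
default; the radial extent is a config knob since published water/ion
maps rarely state it). `boltzmann_invert()` applies
`G(z) = −kT ln n(z)` at T = 310 K (kT = 0.616 kcal/mol) and shifts the
profile to min 0 — the zero line is a convention, so the minimum is the
only assertable reference. Because the occupancy is sampled under the
applied field, the profile is *effective-biased*: it includes the bias
by construction and no field correction is attempted.

Two numerical choices: zero-count bins are masked rather than
pseudo-counted (finite barriers are plotted only where sampled), and
across-run aggregation reports per-bin mean and sample SD over runs
where the bin is unmasked in at least two runs. A block-SD alternative
over time blocks of one run is deliberately not the default: the
reference figure's error bars are across runs.

**Validation and sampling power.** The generator's diffusion mode is an
overdamped Euler–Maruyama integrator (step = stride/substeps, default 10
substeps) whose stationary law is exactly `exp(−U/kT)`; recovery of a
planted potential is therefore a pure test of the occupancy/inversion
pipeline. The statistical error on `G` at a bin with expected count `m`
is `kT/√m`, so resolving a 5 kcal/mol (8.1 kT) barrier top to 0.15
kcal/mol needs ≥ 17 counts there — at 2×10⁵ frames that dictates ~24
independent ion samplers, the condition the barrier-sweep test uses. The
acceptance run uses a 2 kcal/mol barrier with 4 ions, where the same
bound is met with a three-fold margin.

## Gate geometry and CTD rotation

Minimum distances between opposing subunits use all atoms of the given
selections (shipped configurations are heavy-atom only); the per-frame
*narrower-pair* reduction takes the smaller of the two opposing-pair
distances — the effective aperture of a four-fold gate. Histograms are
left-closed, right-open, anchored at 0, with fractions above a threshold
counted strictly (`value > threshold`).

The cytoplasmic-domain rotation is the torsion between plane(1,2,3) and
plane(1,2,4), where 1/2 are the centres of mass of the whole TMD/CTD and
3/4 of one subunit's TMD/CTD, referenced to the same torsion in a
reference structure and evaluated per frame (end-state scalars are the
final frame). Counterclockwise viewed from the extracellular (+z) side
is negative, matching the sign of all reference end states. Centres of
mass use unit masses by default — marker-bead topologies carry no
masses — with an optional per-particle weight vector; both modes are
exposed because published values do not state the weighting. The
residue ranges defining "TMD" and "CTD" are likewise configuration
fields (the shipped defaults follow the membrane-boundary annotation of
the channel architecture) and user-overridable.

Superposition is a least-squares rigid fit (SVD with reflection
forbidden); trajectories are aligned on the SF backbone before any
pore-axis analysis. Side-chain inclusion in the published alignment is
unstated; the shipped selection fits Cα/backbone beads of the SF
residues. Dihedrals use the standard IUPAC-signed torsion in
(−180, 180]; cation-π geometry fits the ring plane by SVD and folds the
axis angle to [0°, 90°].

## Hydration and the G-loop cylinder

Water occupancy maps count water oxygens in the pore cylinder per z bin
per frame; the wetting state of a slice is `wet` when its count reaches
a threshold. Hydration numbers count water oxygens within 3.5 Å of an
ion with a *closed* boundary (≤ counts), the convention of the common
trajectory tools. G-loop pass statistics replicate the cylinder
extraction: every (frame, ion) with the ion inside a 4-Å-radius,
4-Å-high cylinder centred on the centre of mass of all G318+M319 atoms
of all four subunits (the atom subset is unstated in published work;
all atoms is the least arbitrary choice) contributes one snapshot of
the narrower-pair gate distance (residues 316–320) and the ion's
hydration number.

## Selectivity-filter mechanism classification

`assign_sites()` maps ions and water oxygens inside the SF cylinder
(4-Å radial cutoff) to sites S4..S0 via left-closed windows between the
six boundary planes, encoding each frame as a string over `{K, W, 0}`
with K taking priority. Site windows derive from the SF oxygen-plane
z-positions when SF atoms exist, else from configuration values. The
T153-level entrance site is treated as part of the cavity compartment,
not a sixth SF site: it appears in occupancy profiles but not in state
strings.

An event is `direct_knock_on` when no frame in its window shows a W
between two K symbols *and* no water co-permeates; `water_mediated`
when every ion–ion gap in every multi-ion frame holds a water; `mixed`
otherwise. An adjacent KK pair is a waterless gap — contact between
ions anywhere makes the event non-water-mediated. Water co-permeation
requires the water's own trace to commit across the SF interval within
the event window ± 1 ns (exits complete within a few ns) *and* to be
observed inside the SF cylinder in both the S4 and S0 windows during
the crossing; the second condition is what "passing through the filter"
means geometrically, and it makes the count immune to bulk waters that
merely span the filter's z range elsewhere in the box or to re-seeded
tracer waters whose teleports could alias into periodic jumps.

## The synthetic pore generator

`generate_pore_trajectory()` emits a labeled trajectory (four-fold
marker-bead scaffold, ions, waters) plus ground truth. It emulates the
statistical structure the analyses care about, not the physics:

* **Geometry**: 80 × 80 × 145 Å box (the 14.5-nm height of a solvated
  Kir system), entrance/G-loop/HBC at z = 30/52/72, five 3-Å SF sites
  spanning 85–100 Å, stride 20 ps (the usual coordinate-output
  interval). Gate-forming side-chain beads sit at the current gate
  radius, so opposing-pair minimum distances read twice the radius;
  F192 Cα beads are fixed at the 15.3-Å crystal-structure diameter.
* **Diffusion mode**: ions follow overdamped Euler–Maruyama dynamics on
  a piecewise-linear U(z) with an optional uniform field
  (force = e·V/L_z), reflecting bounds, and a known stationary law.
  K⁺ diffusivity defaults to 0.2 Å²/ps (bulk experimental value).
  Gate flicker is a two-state Markov process (rates in 1/ns); a closed
  gate blocks z steps across its plane.
* **Rate mode**: transits are scheduled by a Poisson process at a
  configured events/µs; ion paths are piecewise-linear in unwrapped z
  with a per-ion accumulated box offset, so the wrapped coordinate
  shows clean periodic jumps and the planted event list is exact. With
  `sf_single_occupancy`, two resident ions sit at S3/S2 and an arriving
  ion displaces the chain within one frame interval — the direct
  knock-on rule — with the displaced ion clearing its site in the same
  interval so no stored frame ever shows two ions in one site. Initial
  residents are excluded from the planted list: their first exit is not
  a full bottom-to-top crossing of the recorded trajectory.
* **Waters** are non-interacting tracers: region-confined random walks
  reproduce a configured relative density profile (the SF region is dry
  by default), and `solvation_shell` waters are re-seeded within
  2.6–3.4 Å of each ion while the ion is below the SF. This suffices
  for wetting/hydration analyses, which count positions only.

What passing tests therefore show: the detectors, profiles and
classifiers compute what they claim on data whose truth is known
exactly, at realistic geometry and output cadence. What they do not
show: force-field realism, water orientation physics, electrostatics,
or the actual GIRK2 PMF shape — conclusions about real trajectories
still depend on the simulation that produced them.

## Scripted scenarios

Frame-exact, noise-free constructions pin the detectors' edge cases:
one full crossing (exactly one event at each level), sub-margin flicker
(zero events from 20 plane recrossings), a dehydrated single-file chain
(every event direct knock-on), an alternating ion–water file (every
event water-mediated with co-permeating waters), a donor–hydrogen–
acceptor triple at set distance/angle, and a CTD bead cloud rotated by
a set angle (recovered to 0.01°).

## Problem sizes and reproducibility

The shipped test suite and `scripts/acceptance.R` run at desk scale:
2×10⁵-frame diffusion runs for PMF recovery, 5×10⁴-frame rate runs
(1 µs at 20-ps stride) for rate recovery over five seeds per
configured rate, and 10³–10⁴-frame runs elsewhere. Every stochastic
stage is driven by a single integer seed; reruns with the same seed are
byte-identical, which the suite asserts on the emitted files.

## Known limitations

* Waters do not interact with ions or gates; dewetting is imposed by
  the density profile, not emergent.
* The rate-mode knock-on chain is scripted bookkeeping, not Coulomb
  repulsion; it validates detection and classification, not mechanism
  energetics.
* Hydrogen-bond detection on hydrogen-free systems falls back to the
  distance criterion (flagged `implicit_hydrogen`); angle information
  is unavailable by construction.
* Compartment labels are z-only; an ion lingering radially outside the
  pore at gate height is still labelled by its z position. Radial
  cutoffs are enforced where they matter (occupancy, SF assignment,
  cylinder extraction).
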