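---
title: "Quantifying pLGIC gating: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pLGIC gating: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatemetrics)
```

# The measurement model

Pentameric ligand-gated ion channels couple ligand binding in the
extracellular (EC) domain to the opening of a transmembrane (TM) pore
some 60 Å away. The coupling is quaternary: the EC domain twists about
the pore axis, the EC subunits tilt, and the interfacial loops (β1-β2 on
the EC side, M2-M3 on the TM side) transmit the motion to the pore-lining
M2 helices, which constrict the channel at the 9′ position. This package
measures that machinery. Everything reduces to a handful of geometric
constructions on Cα coordinates, so the assumptions are worth stating
precisely.

## The pseudo-symmetry axis

Every observable is referred to an `axis_frame`: origin at the centroid
of all pentamer Cα atoms within the declared EC+TM ranges, z axis the
unit vector from the TM Cα centroid to the EC Cα centroid (membrane
normal, oriented TM→EC). On an exactly C5-symmetric structure this is
the symmetry axis; on real structures it is a cheap, deterministic proxy
for it. We deliberately avoid inertia-tensor axes: their eigenvector sign
is ambiguous and their direction is sensitive to missing loops, whereas
the two-centroid construction degrades gracefully — deleting a
three-residue loop from each chain of the synthetic pentamer moves the
axis by well under half a degree (tested). Missing residues are simply
skipped in all centroids; no modeling is attempted.

## Twist

The per-subunit twist τ_i is the signed angle from the projection of the
TM subunit centroid to the projection of the EC subunit centroid, both
on the plane perpendicular to the axis, with the right-hand rule about
the TM→EC axis fixing the sign; the receptor twist is the mean of the
five τ_i. With this handedness the active→resting transition of the
synthetic receptor is positive. For crystal structures we compare
magnitudes, since the reported experimental values are magnitudes.

## Tilt decomposition (blooming)

Each EC subunit gets a local frame: X the in-plane unit vector from the
axis to the EC subunit centroid (radially outward), Z the axis, Y = Z×X
(tangential). The subunit's principal axis **v** is the
largest-variance direction of its EC Cα cloud, sign-fixed so v·Z > 0;
for rod-like β-sandwich domains this coincides with the inertia-minor
axis while avoiding its sign ambiguity. The polar (radial, "blooming")
tilt θ_p is the signed angle between Z and the projection of v on the XZ
plane (positive = outward lean); the azimuthal (tangential) tilt θ_a the
signed angle between Z and the projection of v on the **YZ** plane. One
published description of this decomposition defines both components via
the XZ plane; that is geometrically impossible (the two components would
be identical), so the tangential component uses the YZ plane, which is
what "tangential" means in this frame. Projections shorter than 1e-6
report a zero component rather than noise.

For the construction v = normalize((tan θ_p, tan θ_a, 1)) used by the
generator, tan² of the total tilt angle equals tan²θ_p + tan²θ_a
exactly, which the property tests exploit.

## Pore size

Two complementary measures:

* The **Cα cross-section** σ at a prime position: the five Cα projected
  on the plane ⊥ axis, ordered by azimuth, area by the shoelace formula,
  reported in nm². For a regular pentagon of circumradius r this is
  (5/2) r² sin 72°, the closed form the tests pin down. It is a pure
  backbone measure, insensitive to side-chain rotamers.
* The **sphere-fit radius profile**: per axial slice z, the radius of
  the largest sphere centered in the slice plane that touches no atom,
  r(z) = max_c min_j (‖c − x_j‖ − r_vdw(j)) with full 3D distances.
  Van der Waals radii default to C 1.85, N 1.75, O 1.65, S 2.00,
  H 1.00 Å (the classic pore-tracing set; configurable). The optimizer
  is a deterministic 0.25 Å coarse grid over a 5 Å disc about the axis
  followed by pattern-search refinement from the best five cells down to
  0.02 Å steps. We chose determinism over the Monte-Carlo annealing of
  classic pore tracers: reproducibility matters more here than exact
  tool compatibility, and the property suite holds the optimizer within
  0.05 Å of an exhaustive 0.05 Å grid oracle on randomized slices. Two
  simplifications are deliberate: the center never leaves the slice
  plane (no z wobble), and hydrogens are excluded. Slices with no heavy
  atom within 15 Å of the axis are *undefined* (`NA`), not zero; fully
  occluded slices clamp at radius 0.

The constriction is the global minimum of the profile over the TM span,
ties resolved at the midpoint of the minimal plateau, and is annotated
with the nearest prime ring (by mean Cα z).

## Solvent occupancy, flux, dehydration

Occupancy counts particles in an axial slab |z − z(9′)| ≤ cutoff
intersected with a pore cylinder (default radius 6 Å) about the axis.
The conventional cutoffs are 2 Å for water oxygens and 5 Å for ions. A
literal 2 Å *sphere* around the constriction point cannot hold the ~6
waters an open pore carries, so the slab∩cylinder reading is the one
implemented; it is a documented interpretation, not a claim about any
other implementation.

A permeation event is a particle translocating from one solvent
compartment to the other through the pore. Compartment state uses
hysteresis: a particle must clear a 5 Å buffer beyond the membrane plane
to change state — functionally equivalent to enlarging the periodic box
by a buffer layer at top and bottom — and the state change only counts
as an event if the intervening path has at least one frame inside the
pore cylinder within the membrane slab. Diffusion around the periodic z
boundary therefore never counts; a crafted wrap-around path is a
regression test. Up and down events are counted without distinction in
the flux (events per ns); directions are retained per event. Membrane
z-bounds default to the axial extent of the TM ranges and are
overridable, since analysis inputs often lack lipids.

The axial water-density profile histograms water oxygens in the pore
cylinder (0.5 Å bins, origin at the 9′ ring), normalized by the bulk
number density measured in the same cylinder beyond 5 Å outside the
membrane slab (the bulk region is split in two by the membrane; both
sides contribute). The dehydrated stretch is the total and longest
contiguous span where normalized density falls below 1/100 — a
non-structural signature of pore closure.

## Interface observables

ΔZ is the axis-projected distance between Cα of the M2-M3 loop proline
(P268) and Cα of the β1-β2 tip (V45), averaged over subunits, reported
unsigned by default (a signed variant exists). The proline projection
superposes the snapshot's TM Cα on a reference (Kabsch), then projects
the residue's heavy-atom center of mass on the membrane plane —
hydrogens are excluded because crystal inputs lack them. Binding-site
distances pair subunits through the declared cyclic interface order:
(+) principal, (−) complementary. The χ rotamer of the 9′ leucine is the
torsion over N–Cα–Cβ–Cγ — the standard χ1 quadruple; an option flag
gives the literal Cα–Cβ–Cγ–N ordering for comparison with descriptions
that list the atoms in that order — with cis assigned at |χ| < 90°, a
decision documented rather than sourced, since published shading of the
cis/trans ranges is not numeric.

## Trajectory statistics

Superposition is the SVD/Kabsch construction with the determinant
corrected to +1, so planar or degenerate selections still return proper
rotations (validated against an independent least-squares fit and an
exhaustive rotation grid). RMSD series fit and measure on the same
domain by default (TM RMSD fits on TM), which keeps domain RMSDs
insensitive to motion of the other domain; cross-fit is available.
Running averages are means over consecutive *non-overlapping* windows
(default 500 frames = 5 ns at 10 ps/frame), not sliding windows.
Autocorrelation times come from an unweighted least-squares fit of
A·exp(−t/τ) to the normalized acf up to lag = half the series, with the
initial τ guess at the first sub-1/e lag.

# The synthetic generator

The toy receptor is a pseudo-atom model, not a polymer: its only purpose
is exact ground truth. Each subunit has four ideal TM helices (rise
1.5 Å, 100°/residue, helix radius 2.3 Å, 18 residues each) and an EC rod
of pseudo-Cα carrying the marker residues on its axis. Residue numbering
mirrors GluCl (9′ = 254, proline 268, tip 45...). Three constructions
make schedule recovery *exact* at zero noise rather than merely close:

* 18-residue helices: the 18 phases are all multiples of 20°, so each
  helix's Cα centroid falls exactly on its axis and the TM subunit
  centroid sits exactly on the subunit meridian — imposed twists recover
  to 1e-9.
* The M2 helix is phased so the 9′ Cα points exactly at the pore axis,
  putting the 9′ ring at exactly the scheduled circumradius — the
  cross-section closed form is exact.
* All EC markers lie on the rod line, and the vertical β1-β2
  displacement slides V45 *along* the (possibly tilted) line with a
  counterweight marker slid oppositely, preserving the EC centroid and
  principal axis exactly — so ΔZ schedules do not contaminate twist or
  tilt.

The default transition schedule is the two-step un-gating scenario:
twist 15.3 → 21.3° and azimuthal tilt 0 → 5° with half-transition at 16%
of the run, 9′ circumradius 7.67 → 6.95 Å (cross-section 1.40 → 1.15
nm²), ΔZ 5 → 7 Å and the proline moving 4 Å inward on the same fast
clock, followed by blooming 7.6 → 10° at 50% — twist completes before
blooming, and the ordering of half-transition times is asserted in the
tests. Logistic segments (width 5% of the run) or linear ramps are
available, as are per-subunit twist offsets. Gaussian coordinate noise
(σ in Å) is added per atom and frame from a single explicit seed; the
caller's RNG state is never touched.

The solvent simulator is a seeded reflected random walk in a periodic
box (defaults 30×30×56 Å): an impenetrable membrane slab (z 18–38 Å)
except inside a pore cylinder of schedulable radius, point particles of
hard radius 1.4 Å, step σ 1.5 Å/frame/dimension — about the z-RMS
displacement of bulk water over a 10 ps frame. Rejected moves leave the
particle in place, which preserves a uniform stationary distribution
over the accessible volume. The default 1090 particles put the
reservoir at liquid-water number density (0.0336 Å⁻³), so the open pore
(accessible radius 5.2 − 1.4 = 3.8 Å) holds ~6 particles in the 2 Å
occupancy slab, the open-state occupancy scale. A pore radius below the
particle radius closes the channel completely: zero slab visits and
zero events, exactly.

What the generator does *not* emulate: excluded volume between
particles, electrostatics, lipids, side chains, secondary-structure
relaxation, or any free-energy landscape — transitions follow imposed
schedules, not dynamics. Passing tests therefore demonstrate that the
observables measure what they claim on known geometry and known
kinematics, not that any particular receptor behaves this way; absolute
toy values (e.g. the Cα-only pore radius) are wider than all-atom
values at the same ring size.

# Numerical choices and degenerate inputs

* Angles are degrees in (−180, 180]; lengths Å; cross-sections nm²;
  times ps (fluxes per ns). Coordinates are crystal numbering, 1-based,
  per chain.
* Degenerate geometry (coincident EC/TM centroids, subunit centroid on
  the axis, projections under 0.1 Å for twist) raises errors naming the
  construction; sub-1e-6 tilt projections return 0 for that component.
* The pore profiler reports `NA` for slices with no nearby atoms, and
  the constriction search ignores them; an all-`NA` span is an error.
* Block averages drop the trailing partial window; a window longer than
  the series is an error, not a silent mean.
* Recovery tests at σ = 0.5 Å compare running-averaged series (25-frame
  windows over 250 frames) against the schedule, mirroring how every
  reported time series is smoothed before reading off values; the raw
  per-frame noise of a five-point ring area or a five-pair ΔZ exceeds
  what any per-frame estimator could promise.
* Problem sizes in the test and acceptance runs — 250-frame transitions,
  1500-frame solvent runs at ~1100 particles, 10⁴-frame closed-pore
  runs at 150 particles, 5000-frame AR(1) series — were chosen as the
  smallest sizes at which the stochastic checks have comfortable
  margins.

# Known limitations

* The pseudo-symmetry axis and the domain ranges are conventions;
  absolute twist/tilt values shift by fractions of a degree under
  different conventions, which is why cross-structure comparisons
  should use one topology config throughout.
* The sphere-fit profiler is not a drop-in replacement for
  simulated-annealing pore tracers: no z-wobble, fixed radius set,
  in-plane centers. Differences are within a few tenths of an Å for
  smooth pores but can grow in highly tortuous channels.
* DCD is the only trajectory format (read via bio3d, written by a
  minimal single-precision writer); XTC is not supported.
* The permeation counter requires one frame inside the pore during a
  crossing; particles faster than roughly a membrane thickness per
  frame would be undercounted. At realistic frame spacings this does
  not occur.
* Ligand-restraint distances need explicit ligand residue identifiers;
  no automatic ligand detection is attempted.
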