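---
title: "Modelling host–guest inclusion complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling host–guest inclusion complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclodyn)
```

## The problem

Cyclodextrins are cyclic oligosaccharides whose truncated-cone cavities
host small hydrophobic molecules; whether and how a guest such as eugenol
(a phenol derivative from clove oil) sits inside the cavity governs its
solubility and stability.  `cyclodyn` models this complexation at the
molecular-mechanics level: a classical force field evaluates the
host–guest energy, an exhaustive scan over guest positions and
orientations maps the energy landscape, and rigid-body molecular dynamics
simulates the approach, residence and escape of the guest at a fixed
temperature.

## The energy model

The total energy is the sum of intermolecular and intramolecular parts,
in the AMBER functional form.  The intermolecular part sums three terms
over all host–guest atom pairs, with **no distance cutoff** (the system
is small and non-periodic):

* **Lennard-Jones** `A_ij/R^12 − B_ij/R^6`.  Per-type coefficients are
  combined geometrically, `A_ij = sqrt(A_i A_j)` and
  `B_ij = sqrt(B_i B_j)`, the classic AMBER convention; parameter tables
  may instead give a like-pair well depth ε and minimum distance r_min,
  converted as `A = ε r_min^12`, `B = 2 ε r_min^6`.
* **Continuum-dielectric electrostatics** `q_i q_j k_C / (ε R)` with the
  Coulomb constant k_C = 332.0637 kcal Å/(mol e²).  Water is a uniform
  medium with ε = 80; this is the only way the solvent enters, so the
  hydrophobic contribution to binding is *not* modelled.  The 1/ε
  scaling is exact and is asserted by a test (ε = 26 reproduces the
  water value times 80/26).
* **12-10 hydrogen bonds** `C_ij/R^12 − D_ij/R^10`, applied only to
  pairs in which one atom is flagged as a donor hydrogen and the other
  as an acceptor *and* the (donor type, acceptor type) pair is
  tabulated.  For those pairs the 12-10 term **replaces** the 12-6 term
  (AMBER-84 behaviour).

The intramolecular part is the bonded strain only — harmonic bonds and
angles plus the cosine torsion series — evaluated for the guest
conformation (and optionally the host).  Intramolecular *nonbonded*
pairs are deliberately not evaluated: with both molecules treated
rigidly their contribution is a constant, and the decomposition
`E = E_inter + E_intra` stays interpretable.  The host is used at its
input geometry throughout, so any host strain is a constant offset that
is dropped by default.

Units everywhere: Å, elementary charges, amu, kcal/mol and fs
internally; picoseconds in reports.  k_B = 1.9872041e-3 kcal/(mol K), so
k_B T = 0.58225 kcal/mol at the process temperature of 293 K.

## The scan

`mm_scan()` evaluates the energy at every point of a Cartesian lattice
of guest centre-of-mass positions for every orientation in an
`orientation_set`, recording the per-point minimum.  The reference
protocol is a −5..5 Å grid at 0.1 Å spacing with ~23,000 orientations;
the default orientation generator is a regular lattice over the
intrinsic Z-Y′-Z′′ Euler angles, 36 × 18 × 36 = 23,328 points, chosen
over random sampling for exact reproducibility (a seeded uniform-random
scheme is also provided).  β is sampled at cell midpoints so no lattice
point sits at a pole.  Tests and examples use coarser grids (0.5–1 Å,
tens to hundreds of orientations): the properties asserted — plane
minima, symmetry, bracketing — are resolution-independent, and the
package treats the full-resolution scan as a long-running reproduction
mode rather than a test case.

Derived products:

* `penetration_potential()` reports W(Z), the minimum **intermolecular**
  energy over each Z = constant plane, with the components of the
  minimizing configuration.
* `boltzmann_pes()` reports the per-point Boltzmann-weighted mean energy
  over orientations.  "Average Boltzmann energy" is read as the energy
  expectation `Σ E_i w_i / Σ w_i` with `w_i = exp(−E_i/k_B T)`, not the
  free-energy-like `−k_B T ln Σ exp(−E_i/k_B T)`; the expectation lies
  between the per-point minimum and the arithmetic mean, which is
  asserted as an invariant.  The average uses the same total energy E as
  the minima, at the process temperature 293 K.  Accumulation is
  streaming with a running-minimum shift, so no energy range can
  overflow the exponentials.  The host's Z extent is divided into four
  equal slabs (~2 Å for the default host) from narrower to wider rim,
  and each slab's surface is the per-(X,Y) minimum of the average.
* `global_minimum()` returns the lattice minimizer; ties are broken
  lexicographically by (Z, X, Y, orientation index) so results are
  deterministic across execution orders.
* `classify_inclusion()` calls a configuration an inclusion complex when
  any guest atom lies within the host's Z extent and inside the linearly
  interpolated cavity radius at its Z.

Numerical guards: pair distances are floored at 0.1 Å and per-point
energies clamped at 10^6 kcal/mol; points where every orientation
clashes are flagged rather than silently kept.

## Rigid-body dynamics

The guest moves as a rigid body in the field of the fixed host: the
centre of mass follows the total force, the orientation follows the
total torque.  Orientations are unit quaternions, which avoid the
gimbal singularity of Euler-angle equations of motion.  The integrator
is a leap-frog variant for constant-temperature simulation:

* Translational half-step velocities are updated from the COM force;
  with the thermostat on, a per-step scalar rescale pins the
  translational kinetic energy exactly at 3/2 k_B T.
* Angular momentum is propagated in the **lab frame**, where it is
  exactly conserved at zero torque — this keeps million-step free-rotor
  runs stable, which a body-frame Euler-equation update (explicitly
  integrating the ω × L precession term) is not.  The body-frame angular
  velocity obtained through the current orientation drives the
  quaternion advance (exact constant-ω rotation over the step), followed
  by renormalization; the norm stays within 1e-8 of unity over 10^6
  steps by test.
* The rotational kinetic energy is rescaled to its own equipartition
  target each step.  Linear guests have a degenerate inertia axis; such
  axes are excluded and the rotational target counts only the live
  degrees of freedom (k_B T for a rod, 3/2 k_B T otherwise).
* With the thermostat off the step reduces to plain leap-frog:
  the harmonic-probe period is reproduced to 0.1%, total energy drifts
  by less than 1e-3 kcal/mol over 10^5 steps, and reversing the
  (properly re-staggered) velocities retraces the path.

Initial conditions follow the four canonical dispositions: the guest COM
on the cavity axis 1 Å beyond the narrower or wider rim plane, with
either the "radical" end (body +X) or the "phenyl" end (body −X)
pointing into the cavity; the spin about the approach axis and the
directions of the initial velocities are drawn from a seeded generator,
while the velocity magnitudes are fixed exactly by the temperature.
The time step is 1 fs and every 100th step is registered, i.e. 0.1 ps
sampling.

A trajectory ends when the guest is outside the host envelope — a
cylinder of the larger rim radius + 2 Å spanning the host Z extent
+ 2 Å margins — *and* the intermolecular energy is no longer attractive
enough to pull it back, taken as E_inter > −k_B T, sustained over 50
consecutive sampled frames.  Neither the envelope margin nor the
attraction threshold has a canonical value; both are explicit arguments.
A hard `max_steps` cap flags unterminated runs instead of looping
forever.

## Observables

* `residence_time()` totals the sampled time with E_inter below the
  threshold (default −k_B T): the time the pair is bound, inside or
  outside the cavity.
* `position_density()` histograms sampled COM positions into half-open
  voxels (0.5 Å by default; the analysis grid is a free choice) and
  normalizes by the total frame count.  Positions outside the grid go to
  a reported overflow tally rather than being dropped.  Projections are
  exact marginal sums, and subset densities (by start region or heading)
  mix back into the full density with count weights — both asserted as
  identities.
* `binding_free_energy()` implements
  `F = −k_B T ln Σ_i exp(−W_i/k_B T)` by log-sum-exp.  W_i is the total
  complex energy of each registered frame.  The sum is taken **per
  trajectory** and then averaged into F_mean: the per-trajectory reading
  matches reporting a range of F values across a simulation, which a
  single pooled sum could not produce.
* `summarize_trajectories()` reports E_mean as the frame-weighted mean
  of per-frame totals (components alongside), and F_mean/t_mean as
  unweighted means of per-trajectory values.

## Synthetic systems

The generators in `make_toy_host()`/`make_toy_guest()` emulate the
geometry that matters — a truncated-cone cavity of dispersive sites
(rims 4 and 5 Å, height 8 Å, 4 rings × 8 sites by default) and a rod
guest (3 sites, 1.5 Å apart) — with optional charges, donor/acceptor
flags and a zig-zag torsion variant so that every force-field code path
is exercised.  The like-pair LJ well depth (0.2482 kcal/mol at
r_min = 4 Å) is fixed so that the default guest's cavity minimum is
about −10 kcal/mol, an energy scale representative of a real
cyclodextrin complex; the well depth is exactly linear in that ε, so the
constant is determined by a single scan.  What the toy systems do *not*
emulate: chemical detail of glucose units, directional hydrogen-bond
geometry, guest flexibility beyond one torsion, and any solvent
structure.  Passing tests therefore demonstrate the correctness of the
machinery — energies, derivatives, integrators, estimators — not
agreement with any experimental system.

A synthetic β-cyclodextrin/eugenol pair is packaged for end-to-end runs
on a chemically realistic composition: conformers from distance-geometry
embedding (the macrocycle constrained to a regular heptagon of
glycosidic oxygens), Gasteiger charges, and an element-class parameter
table.  The embedded torus's cavity is tighter than the crystallographic
cavity, so with this asset the guest binds at the rims rather than
inside; it is a loading/plumbing fixture and a starting point for users
with better coordinates, not a quantitative reproduction input.

## Design choices

* **Euler convention**: intrinsic Z-Y′-Z′′, stated everywhere it
  matters; quaternions are `(w, x, y, z)` mapping body to lab frame.
* **Host frame**: origin at the host COM; Z is the principal axis whose
  inertia moment is most isolated from the other two.  A symmetric top
  has two near-equal moments, and the odd one out belongs to the
  symmetry axis — the smallest for a tall cone, the largest for a flat
  torus; the isolation rule covers both without a shape switch.  +Z
  points toward the wider rim (larger mean radial distance), so
  "narrower rim" is always −Z.
* **Guest rigidity in MD**: the equations of motion drive only the COM
  and orientation; the bonded intramolecular energy of the rigid
  conformer is a constant reported per frame.  Propagating internal
  torsions would need its own integrator and is out of scope; the
  consequence is that E_intra cannot fluctuate along a trajectory.
* **Determinism**: every stochastic element (orientation sampling,
  initial spins, initial velocity directions) flows from explicit seeds;
  identical seeds give bitwise-identical trajectories, asserted by test.

## Problem sizes

The test suite runs scans at 0.5–1 Å spacing with ≤ 500 orientations,
trajectories of 10^3–10^5 steps, and the two long integrator checks
(10^5-step energy conservation, 10^6-step quaternion hygiene); the
acceptance script runs the 0.5 Å/500-orientation scan and twelve
trajectories capped at 600,000 steps.  These sizes were chosen so the
full pipeline, including its slowest invariants, runs comfortably on a
single CPU while still exercising every code path at meaningful scale.

## Known limitations

* Continuum dielectric only: no hydrophobic effect, no explicit water,
  no polarization, no generalized-Born electrostatics.
* Rigid host and rigid guest; conformational adaptation enters only
  through the constant bonded strain of the input conformers.
* Scan minima are lattice minima — no continuous local minimization is
  run on top of the grid.
* The packaged cyclodextrin conformer is synthetic and its cavity is
  too tight for interior inclusion of the packaged eugenol conformer.
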