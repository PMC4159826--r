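---
title: "Methods: coarse-grained electrokinetic translocation of ssDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained electrokinetic translocation of ssDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poredyn)
```

## The physical model

`poredyn` simulates a long single-stranded DNA molecule driven through a
rectangular nanopore embedded in a nanofluidic channel. The molecule is a
coarse-grained bead-spring chain: a 48 knt ssDNA is mapped onto N = 400 beads
(120 nt per bead) joined by harmonic springs,

U_bond = (k/2) (r_ij − r_eq)²,

with equilibrium bond length r_eq = α r_nt N_nt / N. With the internucleotide
distance r_nt = 0.43 nm, a contour-scale factor α = 0.847 and the default
counts this gives r_eq = 43.7 nm. The spring constant k = k_B T / χ² is set by
the thermal bond-fluctuation length χ = 0.1 σ. Excluded volume between
non-adjacent beads uses the purely repulsive Weeks–Chandler–Andersen form: the
Lennard-Jones potential with σ = 5 nm (the ssDNA persistence length) and well
depth ω = k_B T, shifted up by ω and truncated at 2^{1/6} σ, so force and
energy vanish continuously at the cutoff. The truncation radius is the only
value for which the interaction is purely repulsive with a continuous force,
which is what the volume-exclusion term is for; the same form, evaluated on
the perpendicular distance to each wall face, gives the bead–wall repulsion
("mirror" rule: the wall force acts only along the surface normal).

Each bead carries a friction coefficient and an effective charge matched to
bulk transport measurements through the Einstein relation:

- ζ = k_B T / (N D) = 4.69 × 10⁻¹² kg/s per bead for D = 2.21 × 10⁻¹² m²/s
  (the printed value 4.68 × 10⁻¹² follows from a two-digit Boltzmann
  constant; the package uses CODATA k_B throughout),
- Q = −μ k_B T / (N D) = −0.83 e per bead for μ = 2.84 × 10⁻⁸ m²/Vs.

The charge is an *effective* charge that already includes counterion
screening, which is why it is far below one elementary charge per nucleotide.
Hydrodynamic coupling between beads is neglected, consistent with treating
each bead as an independent friction centre.

## Overdamped dynamics

Inertia is irrelevant at these scales, so the equation of motion is the
overdamped Langevin equation: ζ v_i = F_i + R_i, integrated with the explicit
Euler scheme at Δt = 10 ps. The random force R_i has independent Gaussian
components with variance 2 ζ k_B T / Δt per component — the Itô
discretization of delta-correlated thermal noise — so equilibrium statistics
come out right: the package verifies that a tethered bead samples the
harmonic-well variance k_B T / k and that a free bead's mean-square
displacement grows as 6 (k_B T/ζ) t.

Numerical safeguards, all inert in normal operation:

- per-step displacements are capped at σ/2 (only deep, thermally improbable
  overlaps can produce larger steps through the r⁻¹³ force);
- if a step would still carry a bead through a wall, the position is
  mirror-reflected across the crossed face; if no consistent reflection
  exists (corner cases), the move is rejected. Both events are counted and
  reported on the trajectory object.
- bead–wall distances entering the WCA force are floored at 0.2 σ to avoid
  floating-point overflow; the reflection rule is what actually guarantees
  containment.

Neighbour search for the excluded-volume term uses a Verlet list with a 2 σ
skin, rebuilt whenever accumulated displacement could let a pair cross the
cutoff; because the bond length (43.7 nm) far exceeds the cutoff (5.6 nm) the
lists are almost always empty and the search is a small fraction of the step
cost. The user-facing `excluded_volume_forces()` offers a spatial-hash cell
list and an all-pairs reference that accumulate in identical order, so their
results are bit-identical — this is tested, and it pins down the correctness
of the fast path.

The thermal noise inside the integrator is generated by a dedicated
`mt19937_64` stream seeded from the integrator configuration, so a trajectory
is bit-reproducible given its seed and independent of R's global RNG state;
chain generation uses R's RNG under a locally seeded scope.

## Initial configurations

Equilibrating a 17.5 µm chain dynamically would take of order its Rouse time
(milliseconds), so initial coils are generated directly: a random walk of
fixed bond length whose successive bond directions follow a Fisher
distribution with mean deflection cosine c fixed by the discrete
worm-like-chain (Kuhn) relation (1+c)/(1−c) = 6 l_p / r_eq, with persistence
length l_p = σ. This makes the ensemble root-mean-square radius of gyration
equal √(l_p L_c) with L_c = N r_eq — about 296 nm for the default chain, the
"coil of roughly 300 nm" regime. Because r_eq > 6 l_p, c is negative
(slightly anti-correlated bonds): the coarse bond is longer than the Kuhn
segment it represents. Non-adjacent beads closer than σ are rejected and
resampled, with a bounded restart budget. Translocation runs start with the
coil centre of mass one ensemble R_g before the channel entrance, centred in
y and z.

## The driving field

The electrostatic potential solves the Laplace equation ∇²φ = 0 on the fluid
domain — two reservoirs, the channel, and the pore — with insulating walls
(n·∇φ = 0) and fixed potentials (−0.4 V cis, +0.4 V trans) on electrode
planes 2.5 µm outside the channel entrances. There is no Poisson–Boltzmann
screening or electro-osmotic flow: the pure Laplace problem captures the
geometric focusing of the field by the constriction, which is the effect
under study.

The solver is red–black successive over-relaxation on a masked regular
lattice with ghost-node mirroring for the Neumann walls (a standard
second-order treatment). Nodes own finite-volume cells: the lattice is
cell-centred along the channel axis, and the lateral node offset is chosen so
the *pore* walls land exactly on cell faces (the pore area controls the field
there quadratically); wider walls may be represented up to half a cell
inward, a ≤1% error on the channel cross-section at the default 10 nm
spacing. The converged solution conserves the discrete axial flux through
every cross-section to the solver tolerance (default max residual 10⁻⁹ V),
which is the lattice analogue of current conservation and the main
correctness invariant; a two-segment duct additionally reproduces the 1-D
series-resistor field ratio, and the solution is gauge invariant. Over-
relaxation uses ω = 2/(1 + sin(π/n_max)), near-optimal for the lattice, with
a linear-in-x initial ramp.

Forces on beads interpolate the nodal potential gradient trilinearly with
mask weighting (solid nodes get zero weight), giving a continuous field that
is exact for linear potentials. Outside the lattice (deep reservoir) the
field decays to the boundary value; reservoir walls exert no force on the
chain — at coil scale they are far away, and the coil may legitimately
overhang the reservoir box before entry.

## Observables and estimators

**Diffusion.** The Einstein-relation estimator fits the ensemble-mean
mean-square displacement of the chain centre of mass against lag time and
divides the slope by 6. The MSD is averaged over time origins within each
trajectory (the standard practice for simulated tracks) as well as over the
ensemble; the first 5% of lags are excluded as transient, and the default
maximum lag is 10% of the trajectory (short lags carry most of the
information for Brownian motion). The standard error comes from the spread of
per-trajectory slopes — correlated MSD points make the naive regression error
meaningless. For the default chain the centre of mass is exactly Brownian
with D = k_B T/(N ζ) = 2.21 × 10⁻¹² m²/s, because internal forces cancel in
the sum.

**Mobility.** Under a uniform field the drift velocity is the least-squares
slope of the ensemble-mean displacement projected on the drift direction;
μ = v/E. For the default parameters μ = |Q|/ζ = 2.84 × 10⁻⁸ m²/Vs exactly.

**Pore occupancy and fold states.** A bead is inside the pore when its x
coordinate lies in the half-open pore interval (y and z are ignored — the
chain cannot bypass the pore). The occupancy clock re-zeroes at first entry
and the series ends when the chain has left. Fold classification uses the
unfolded single-strand baseline b — the mode of the occupancy histogram
restricted to counts below 1.5 × the geometric estimate
(pore_length/r_eq + 1) — and labels a frame m-fold when its count is nearest
(m+1) b: an m-fold configuration threads m+1 strands through the pore.

**Velocity profiles.** Centre-of-mass velocities are central differences at
the recording stride, averaged in bins of the centre-of-mass position x_G;
empty bins are reported as gaps, never interpolated.

**Reduced theory.** Two closed forms summarize the transport: during entry,
dv_G/dx_G = |Q| E_channel (ΔN/Δx) / (N ζ) — the chain feeds beads into the
nearly uniform channel field at a constant rate; after the occupancy reaches
steady state, v_G = |Q| (N_pore E_pore + (N − N_pore) E_channel)/(N ζ), the
field-weighted partition of beads between pore and channel, which reduces
exactly to μE when both fields are equal. With the tabulated inputs for the
30×30 and 40×40 nm² pores these give 3.53 and 4.41 mm/s (printed: 3.54 and
4.41; no rounding of Q and ζ reproduces all printed digits simultaneously,
so agreement is asserted to one unit in the last printed digit). For the
50×50 nm² pore the same arithmetic gives 5.41 mm/s against a printed
5.49 mm/s (~1%), a discrepancy inherited from the rounded tabulated inputs
and left as such. The measured entry slopes reported alongside those tables
(9.1–9.8 × 10³ s⁻¹) exceed the entry-formula arithmetic with tabulated inputs
(≈7.6 × 10³ s⁻¹); both numbers are exposed and neither is forced onto the
other — the likely cause is field non-uniformity near the entrance, which the
one-field entry formula ignores.

## The scaled-down study system

Reproducing the full translocation statistics (20 runs × ~10⁸ steps) is not
a desk-scale computation, so the package ships a 10×-scaled system used by
the test suite for the qualitative and closure claims:

- chain: 480 nt on 40 beads (12 nt per bead, r_eq = 4.37 nm), same per-bead
  ζ and Q as the full chain, σ and ω unchanged;
- geometry: 220 × 50 × 15 nm channel, 20 nm long 15 × 15 nm² pore at
  x = 100–120 nm, 250 × 400 × 50 nm reservoirs, electrodes at ±0.4 V.

Keeping σ at 5 nm keeps the bead physics (wall layers, fold spacing)
realistic while every geometric length shrinks tenfold; the unchanged 0.8 V
bias over a 10× shorter domain strengthens the fields tenfold, which
shortens translocation to ~10 µs and desk scale. The pore still holds ~5.6
beads of a single strand, so the quantized occupancy levels survive, and the
pore-to-σ ratio (3 instead of 6) keeps folded entries possible but rarer
than in the wide pores. On this system the suite checks stepwise occupancy
with a dominant unfolded level, near-linear entry acceleration followed by
saturation, and a terminal velocity within 20% of the field-partition
formula evaluated with the measured occupancy and solved fields (the
simulated velocity runs ~10% above it, mainly because the pore-centre field
underestimates the field averaged over the pore and its mouths).

## Ensemble sizes and statistical design

The stochastic checks fix their ensemble sizes in advance by power analysis
on exact-distribution synthetic tracks (`make_fixture("synthetic_brownian")`
— Gaussian increments with known D, no integrator involved): with 30 runs of
1 µs and a 0.05 maximum lag fraction the diffusion estimate has a ~3%
relative standard error, putting the 10% acceptance band at z ≈ 2.5; the
mobility check with 30 runs has ~1.5% standard error against a 5% band. The
harmonic-well variance check uses Δt = 2 ps and 10⁷ steps so that the Euler
discretization bias (k Δt/2ζ ≈ 0.2%) and the sampling error (~1%) sit well
inside the 3% tolerance.

What the synthetic generators do *not* emulate: sequence heterogeneity,
hybridization or secondary structure, hydrodynamic coupling, electro-osmotic
flow, ionic-current signals, and wall surface charge. Passing tests
therefore validate the coarse-grained transport model and its numerics, not
base-resolution DNA behaviour.

## Known limitations

- The full-scale translocation observables (millisecond trajectories of the
  400-bead chain) are supported by the machinery but not exercised by the
  default test suite; the scaled system stands in for them.
- Tabulated point values of E_channel and E_pore depend on the original
  meshing and sampling conventions; the package asserts their trend and
  order of magnitude, not the printed numbers.
- The 20 × 20 nm² pore preset reproduces the failure-to-enter scenario only
  qualitatively (no quantitative reference row exists for it).
- Electrode planes sit half a lattice cell inside their nominal positions;
  at 10 nm spacing this shifts fields by ≲0.5%.
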