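---
title: "Methods: evaluating oriented electric-field effects on reaction barriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating oriented electric-field effects on reaction barriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oefield)
```

## The physical model

A uniform electric field $\vec F$ perturbs a molecule's electronic energy as
a power series in the field,

$$E(\vec F) = E(0) - \vec\mu \cdot \vec F - \tfrac12 \vec F^\top \alpha \vec F - \dots$$

with dipole moment $\vec\mu$ (the first-order response) and polarizability
$\alpha$ (second order). Hyperpolarizability and higher terms are outside
this package's scope; over the field range treated here (up to
$10^{-2}$ a.u., roughly 5 V/nm) the first two terms dominate for small
organics, which is also why barrier-vs-field curves are expected to be
near-linear with slight curvature.

For a reaction step connecting a local minimum (the nearest starting
material or intermediate stationary point, zero imaginary vibrational modes)
to a transition state (a first-order saddle point, exactly one imaginary
mode), the field changes the two stationary-point energies by different
amounts, so the activation barrier shifts by

$$\Delta\Delta E^\ddagger(\vec F) \approx -(\vec\mu_{TS} - \vec\mu_{Int})\cdot\vec F = -\Delta\vec\mu^\ddagger\cdot\vec F$$

to first order. $\Delta\vec\mu^\ddagger$ is the *reaction dipole*; its unit
vector, the *reaction axis* $\hat\mu^\ddagger$, points along the flow of
electron density during the transformation and is the field orientation to
which the barrier is most susceptible. The package's central claim to test
for any given reaction is therefore: apply fields of increasing magnitude
along $\hat\mu^\ddagger$, and the barrier should fall linearly with slope
$-\lVert\Delta\vec\mu^\ddagger\rVert$ (in converted units), with curvature
bounded by the polarizability difference.

### Sign conventions

Internally the package uses the physics convention throughout: interaction
energy $-\vec\mu\cdot\vec F$, so a field parallel to $\Delta\vec\mu^\ddagger$
*lowers* the barrier. Some quantum-chemistry input formats define the
positive field direction with the opposite sign; that negation is applied
only at the file-writer boundary (`write_gaussian_input()`) and in
`field_vector(..., convention = "gaussian")`, never inside the algebra. One
constants table (`oef_constants()`) owns every unit conversion:
1 D = 0.3934303 a.u. of dipole, 1 Hartree = 627.5095 kcal/mol, and the
bohr–Angstrom factor.

## Why Z-matrix frames, and which one

A fixed-direction field is only meaningful if the molecule cannot rotate
relative to it during optimization. Internal-coordinate (Z-matrix)
optimizations pin the orientation: atom 1 sits at the origin, atom 2 on an
axis, atom 3 in a coordinate plane. The package adopts the standard
orientation — atom 1 at the origin, atom 2 on the $+z$ axis, atom 3 in the
$xz$ half-plane with $x \ge 0$ — which removes all six rigid degrees of
freedom using exactly three atoms. A stricter convention sometimes quoted
(atom 4 on the $y$ axis) cannot hold for general rigid geometries, since
three atoms already exhaust the rotational freedom; we treat such phrasing
as shorthand for an internal-orientation convention and do not replicate it
literally.

Because the minimum and the transition state orient *differently* when
converted to their Z-matrix frames, the reaction axis (computed in the
shared aligned Cartesian frame) must be mapped into each structure's frame.
`orient_to_zmatrix_frame()` returns the proper rotation + translation it
applied; `map_axis_to_frame()` applies the rotation alone, since dipoles are
direction objects. The frame rotation between the aligned and Z-matrix
orientations of the same rigid structure is unique, which is what makes this
mapping well defined.

The Z-matrix itself uses simple-chain connectivity: entry $i$ is defined
against atoms $i-1, i-2, i-3$. This is deterministic and needs no
bond-perception heuristic; choosing an atom order that makes the chain
chemically sensible is exactly the job of the reorder methods. Reference
angles within $10^{-3}$ degrees of 0/180° are recorded as quality warnings
(not errors): they make the dihedral column ill-conditioned.

## Engine contract and frame bookkeeping

Engines are pluggable through four generics (`engine_evaluate`,
`engine_optimize`, `engine_permute`, `engine_transform`). One rule keeps the
geometry stream coherent: **an engine returns results in its own coordinate
frame, and only the workflow applies rigid motions** — superposition and
Z-matrix orientation — transforming the engine alongside via
`engine_transform()`. An engine that silently re-oriented its output would
apply a rigid motion the axis bookkeeping could not see, corrupting both the
recorded frame rotations and (for the toy engine) the harmonic reference
term. This is why `toy_engine`'s optimizer returns the raw analytic optimum
rather than a re-oriented copy.

### The toy engine

The analytic engine assigns each atom a fixed point charge $q_i$ and tethers
it harmonically (force constant $k$) to a reference geometry $r^0$:

$$E(r, \vec F) = E_0 + \tfrac{k}{2}\sum_i \lVert r_i - r_i^0\rVert^2 - \mu(r)\cdot\vec F - \tfrac12 \vec F^\top\alpha\vec F, \qquad \mu(r) = \sum_i q_i r_i.$$

Everything has a closed form: the optimum is $r_i^* = r_i^0 + (q_i/k)\vec F$
and the optimal energy is
$E_0 - \mu(r^0)\cdot\vec F - \frac{\sum_i q_i^2}{2k}\lVert\vec F\rVert^2 - \tfrac12\vec F^\top\alpha\vec F$.
The model reproduces the features the workflow must handle — a
geometry-dependent dipole, second-order curvature, field-induced geometric
distortion scaling as $F/k$ — while every pipeline output can be checked
against exact arithmetic. As $k \to \infty$ (rigid limit) with $\alpha = 0$,
the barrier change reduces exactly to the first-order law, which is how the
test suite verifies slope recovery. Transition-state engines carry a flag
(`ts_axis`) giving them one negative-curvature mode, so the imaginary-mode
success check (0 for minima, 1 for transition states) is exercisable.

## Pipeline parameters

| parameter | default | units | rationale |
|---|---|---|---|
| field magnitudes | 0, 2.5, 5.0, 7.5, 10 ×10⁻³ | a.u. | range where response is near-linear; each optimization is seeded from the previous magnitude's optimum to keep per-step perturbation small |
| reorder method | 0 | — | no reordering; methods 1/2 exist for unstable frames |
| R² success threshold | 0.95 | — | near-linearity criterion for a trustworthy run |
| RMSD warning | 10 | % of reference radius of gyration | flags possible mechanism change, fragmentation or field-induced distortion |
| RMSD jump threshold | 0.05 | Å | step-to-step geometric discontinuity |
| axis degeneracy threshold | 10⁻³ | D | below this, the "optimal orientation" is numerically meaningless |
| orientation-scan directions | 20 | — | dodecahedron vertices |

The RMSD percentage needs a denominator that no common convention fixes; we
normalize by the reference structure's unweighted radius of gyration, which
is scale-free across molecule sizes, and always report the raw Angstrom
value alongside so the table remains comparable with absolute-deviation
conventions.

### Reorder methods

*Method 0* leaves the order untouched. *Method 1* moves the four atoms
nearest the unweighted Cartesian center of the transition structure into
positions 1–4 in ascending distance order (ties to the lower original
index): core atoms are expected to displace least under the field, making
the orientation frame stable. Since four orientation positions exist, four
atoms are moved, even where looser phrasings say "three". The ordering is
derived from the transition structure only and the same permutation is
applied to both structures, preserving positional correspondence. *Method 2*
anchors the frame on a spectator: the atom farthest from the transformation
site becomes atom 1, moving together with all atoms after it in the original
order as a contiguous block, so connectivity implied by atom order survives.
The "site of transformation" is the centroid of user-supplied reacting
atoms; absent that, `infer_reacting_atoms()` selects atoms whose interatomic
distance to some partner changes by more than 0.3 Å between the two
structures — a deterministic fallback with explicit user override.

### Success diagnostics

`evaluate_success()` fits ΔE‡ against magnitude by ordinary least squares
(zero-field point included) and reports the standard R². A point is an
energy discontinuity when its residual exceeds 3× a robust residual scale —
the median absolute residual, floored at 0.01 kcal/mol so that an exactly
linear series is never flagged on floating-point noise. The median (rather
than a standard deviation) keeps the scale estimate from being inflated by
the very jump being detected. Geometry discontinuities are step-to-step RMSD
jumps above the configured threshold. Non-convergence truncates the ramp at
the failing magnitude and flags the result rather than aborting: partial
ramps are still informative.

### Orientation scan

`orientation_scan()` validates the reaction-axis assumption empirically:
fields of fixed magnitude (default 5 × 10⁻³ a.u.) are applied along
directions distributed over the unit sphere and the resulting barriers
recorded. For the default 20 directions we use the vertices of a regular
dodecahedron — deterministic, isotropic (vertex sum is zero) and antipodally
symmetric, so first-order effects appear as equal-and-opposite pairs; other
counts fall back to a Fibonacci lattice. The barrier-minimizing direction
should be the sampled direction best aligned with
$\Delta\hat\mu^\ddagger$, which the test suite asserts in the rigid limit. A
degenerate reaction dipole aborts the ramp (there is no axis to follow) but
not the scan, which explores all directions regardless.

## What the synthetic fixtures emulate — and what they do not

`fixture_reaction()` builds a six-atom minimum/transition-state pair for the
toy engine seeded with fixed reference values on the scale of hybrid-DFT
results for a small pericyclic reaction: stationary-point dipoles of ~1.5–2
D (reaction dipole 3.2 D), a barrier near 49 kcal/mol, free energies offset
by a constant thermal correction, and isotropic polarizabilities of 65/70
a.u. (transition states are typically slightly more polarizable, producing
the expected mild curvature). The two stationary points share one reference
geometry and differ in their charge distributions; charges are the
minimum-norm, net-neutral solution of $\sum_i q_i r_i = \vec\mu$
(`solve_charges_for_dipole()`), so the seeded dipoles are reproduced exactly
and the superposition step is exactly the identity. The default force
constant 0.5 Hartree/bohr² is a typical bond-stretch stiffness and yields
field-induced RMSDs of a few thousandths of an Angstrom across the ramp,
the magnitude seen in practice for rigid organics.

These fixtures deliberately do **not** emulate: anharmonicity, real
electronic structure (charge transfer, polarization of the geometry-dipole
coupling), entropy beyond a constant offset, conformational multiplicity, or
optimization failure modes of real quantum-chemistry codes. Passing tests
demonstrate that the *workflow* — frames, algebra, ramp logic, diagnostics,
serialization — is correct, not that any particular real reaction responds
as predicted; for real systems the package generates input decks
(`oefield prepare`, `gaussian_files_engine()`) and parses the resulting
logs, and the DFT-level response is whatever those calculations say.

Synthetic log files (`synthetic_gaussian_log()`,
`fixture_gaussian_logs()`) are formatted like real quantum-chemistry logs
but contain only the records the parser consumes; they exist for round-trip
parser testing and are labelled synthetic throughout.

## Numerical choices

- Kabsch superposition uses the SVD of the cross-covariance with the
  determinant-sign correction, so reflections are never returned; rank-
  deficient (e.g. planar) cases break ties toward determinant +1. Fewer than
  three atoms yield a translation-only fit with a warning.
- Orientation requires atoms 1–3 to be non-collinear (tolerance 10⁻⁶ deg on
  the angle); collinear leading atoms are a hard error directing the user to
  a reorder method.
- All distance ties in the reorder methods break toward the lower original
  index, making every permutation deterministic.
- Report tables carry full double precision; rounding (4 d.p. for Hartree
  and Debye, 2 d.p. for kcal/mol) happens only at CSV serialization, and the
  ΔΔ rows are differences of unrounded values. Note that 4-d.p. Hartree
  energies cannot regenerate 2-d.p. ΔΔ values exactly: 10⁻⁴ Hartree is
  0.063 kcal/mol, larger than the displayed resolution, which is why the
  package never recomputes ΔΔ rows from rounded energies.
- The problem sizes used throughout the test suite (6–8 atom fixtures,
  5-point ramps, 20-direction scans, a few thousand oracle rotation samples)
  were chosen as the smallest sizes at which every property being asserted
  is non-trivially exercised.

## Known limitations

- First-order + polarizability only; reactions dominated by
  hyperpolarizability are outside the model.
- The reaction axis is computed from zero-field dipoles; strongly
  field-dependent reaction axes (large dipole rotation under the field) are
  only caught indirectly, via the linearity and RMSD diagnostics.
- Atom correspondence is positional. There is no graph matching or
  symmetry-corrected RMSD; inputs must be numbered consistently.
- The Gaussian-style adapter writes and parses files; it does not submit,
  schedule, or monitor jobs, and its log parser targets the handful of
  records the workflow needs rather than full log semantics.
- Each (conformer, elementary step) pair must be evaluated as its own run;
  there is no multi-conformer or multi-step orchestration.
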