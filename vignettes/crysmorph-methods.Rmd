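---
title: "Methods: attachment-energy habit prediction and crystal-solvent interface analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attachment-energy habit prediction and crystal-solvent interface analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crysmorph)
```

## Scope and model

`crysmorph` implements the attachment-energy (AE) route to crystal-habit
prediction and the analysis stages that surround it when a crystal grows
from a mixed organic--water solvent. The workflow is exercised end to end on
the calcium minodronate system, Ca(Min)$_2$ -- a calcium bisphosphonate
coordination compound crystallizing in the monoclinic space group $C2/c$ --
whose cell parameters, face list and attachment energies are bundled as
data (`camin2_cell()`, `camin2_face_table()`).

The AE model states that the relative growth rate of a face $(h\,k\,l)$ is
proportional to the magnitude of its attachment energy,

$$R_{hkl} \propto |E_{att}|, \qquad E_{att} = E_{latt} - E_{slice},$$

where $E_{latt}$ is the per-cell lattice energy and $E_{slice}$ the
per-cell energy of an isolated growth slice of thickness $d_{hkl}$. In
solution, adsorbed solvent must be displaced before a slice can attach, so
the effective attachment energy is corrected by the crystal--solvent
interaction (adhesion) energy:

$$E'_{att} = E_{att} - E_{int}, \qquad
  E_{int} = E_{tot} - (E_{cry} + E_{sol}), \qquad
  R'_{hkl} \propto |E'_{att}|.$$

Because adsorption makes $E_{int} < 0$ while $E_{att} < 0$, the correction
always shrinks $|E'_{att}|$: solvents slow faces they stick to, and a face
whose competitors are slowed enough disappears from the habit entirely.

The habit itself is the Wulff construction: the convex body
$\{x : x\cdot n_f \le d_f\ \forall f\}$ with one halfspace per
symmetry-expanded face, the center-to-face distance $d_f$ proportional to
the face's relative growth rate. Facet-area fractions and side ratios are
read off the resulting polyhedron.

## Growth-rate convention for the bundled face table

The bundled Ca(Min)$_2$ face table carries the five morphologically
important forms with their attachment energies. The package's default --
and the convention used by `predict_habit()` and the acceptance script --
derives Wulff distances from $|E_{att}|$, normalized so the slowest face
has rate 1. With the optimized cell this reproduces the reference facet
areas of the vacuum habit to the printed precision (35.10% on
$(2\,0\,\bar2)$, 4.54% on $(0\,0\,2)$):

```{r habit}
shape <- predict_habit(camin2_cell("optimized"), camin2_face_table())
round(facet_area_fractions(shape), 2)
```

Published characterizations of this system also print a separate relative
growth-rate column that is *not* proportional to the attachment energies it
accompanies; used directly as distances it yields a two-face habit
inconsistent with the tabulated areas. We therefore treat the energies as
authoritative and the rate column as derived-but-inconsistent; users who
want any other convention can pass explicit `distances` to
`wulff_construct()`.

## Geometry engine and numerical choices

No computational-geometry dependency is used: the halfspace intersection is
computed facet-by-facet by clipping each supporting plane against every
other halfspace with Sutherland--Hodgman polygon clipping in the plane's 2D
frame. This yields the facet polygon, its area, and absence (zero area)
directly, and is validated in the test suite against a Monte-Carlo
plane-sampling oracle (agreement within 0.5 percentage points at $10^6$
samples).

* The clipping window half-width is $100\times$ the largest distance; a
  surviving facet vertex beyond $0.45\times$ that window signals an
  unbounded intersection and raises an error (as do fewer than four
  halfspaces or normals that do not span 3D).
* Duplicate normals keep the tightest distance; vertices are merged at
  $10^{-8}\times$ the largest distance for the watertight vertex list and
  OBJ export.
* Laue-class form expansion uses integer point-group matrices for $-1$,
  $2/m$ (b-unique), $mmm$, $4/mmm$ and $m\bar3m$; Friedel pairs are always
  included, so any 3D-spanning normal set closes to a bounded body.
* The side ratio defaults to
  $\sqrt{\overline{A}_{a}}/\sqrt{\overline{A}_{b}}$ over mean single-facet
  areas -- a scale-invariant analogue of the edge-length ratio measured on
  crystal photographs; a longest-in-plane-edge variant is available via
  `method = "max_edge"`.

All lattice geometry (volumes, $d$-spacings, normals) is implemented for
the general triclinic cell from the explicit direct/reciprocal bases;
monoclinic and cubic cells are special cases, tested against their
closed-form expressions.

## Energetics

The non-bonded evaluator is a 12-6 Lennard-Jones plus point-charge Coulomb
sum with geometric-mean mixing (the Dreiding convention), an atom-based
van der Waals cutoff defaulting to 15.5 Å, and either a direct Coulomb sum
(finite clusters) or a minimum-image cutoff sum (periodic systems). This is
a deliberate simplification relative to production force fields: no Ewald
summation, no intramolecular terms (molecules are rigid; intramolecular
pairs are excluded by default), no hydrogen-bond term, and no charge
derivation -- charges are inputs (the bundled water template carries
$q_O = -0.72\,e$, $q_H = +0.36\,e$). Consequently the package makes no
claim to reproduce absolute kcal/mol values from commercial force fields;
the testable surface is the energy *algebra* (the defining identities, the
sign structure, and agreement with brute-force oracles), which is exact.

Two practical cautions are built in. The minimum-image convention requires
the cutoff not to exceed half the smallest periodic box height; violations
raise an error rather than silently truncating. And a cutoff placed exactly
on a coordination-shell distance makes shell inclusion a floating-point
tie; the toy-lattice tests therefore place cutoffs between shells.

`attachment_energy_toy()` evaluates $E_{latt}$, $E_{slice}$ and their
difference per unit cell on toy periodic crystals (axis-aligned slices),
and matches an explicit direct lattice summation to $10^{-6}$ relative.
The `area_scale` argument of `modified_attachment_energy()` exposes the
normalization needed when a box-level $E_{int}$ is subtracted from a
cell-level $E_{att}$ (default 1, i.e. energies already on a common
footing); every pipeline report logs the value used.

## Interface models

`pack_solvent_box()` fixes the box thickness from the target density,
$t = nM/(N_A\,\rho\,A)$, and fills it by seeded random sequential insertion
of rigid molecules (uniform random positions and quaternion-uniform
orientations) with a 1.5 Å minimum intermolecular atom distance and a
0.75 Å clearance to the box faces, so stacked layers never produce
sub-1.5 Å contacts. This is a geometric packing, not an equilibrated
liquid: it gives exact densities and reproducible geometry, which is what
the downstream desk-scale tests need, but no realistic liquid structure.
`assemble_interface()` stacks slab, organic layer, water layer and a
vacuum gap (default 100 Å, suppressing spurious periodic-image
interactions) along $+z$; at equal cross-section the organic/water
thickness ratio equals their volume ratio (the reference protocol uses
1/3). `cleave_slab()` keeps whole molecules whose centroids fall within
the requested depth (default twice the relevant $d$-spacing), avoiding
severed bonds; the surface normal is $+z$, the slab bottom at $z = 0$, and
`surface_edge_z` records the top of the crystal material.

Surface roughness is quantified as $S = A_{acc}/A_{hkl}$ with two
estimators. The primary one, `solvent_accessible_ratio()`, grid-marches the
upper envelope of probe-inflated atom spheres over the periodic
cross-section and triangulates it; it measures the *top* surface only, so a
flat dense layer gives $S \to 1$ and every cavity or adatom raises it. The
complementary `probe_accessible_area()` is a Shrake--Rupley-style total
accessible sphere area for finite systems (an isolated atom gives exactly
$4\pi(r+p)^2$). The probe radius defaults to 1.0 Å -- a Connolly-style
default -- and is configurable; the grid default of 0.25 Å converges the
envelope area for atomic-scale corrugation.

## Density profiles

`mass_density_profile()` bins atom centers (no smearing) into $z$ slabs of
0.5 Å by default and converts to g/cm$^3$ via the in-plane cross-section,
so the integral over $z$ recovers each role's total mass exactly -- this
conservation is regression-tested to $10^{-6}$ (single frame) and
$10^{-3}$ (time-averaged). The default analysis window is the final
quarter of the trajectory, mirroring the emitted protocol's
equilibration/production split (the protocol block's 500 ps run discards
250 ps and analyzes the final 125 ps); the window is configurable because
equilibration judgments are system-specific. `peak_positions()` reports
bin-center positions of local maxima above a noise floor (10% of the
global maximum), tallest first; its resolution is therefore half a bin
width, and the tests size their planted Gaussian layers so that the mode
bin is statistically resolved (thousands of atom samples per layer) rather
than relying on sub-bin interpolation. `surface_overlap()` integrates the
mass fraction below the crystal surface edge with linear partial-bin
weighting.

## Side-ratio statistics

`fit_sideratio()` is ordinary least squares of side ratio on added organic
volume (the observed relationship is close to linear over the working
range); it refuses fewer than three points or degenerate volumes, and
reports a zero $r^2$ for a constant response. `rank_solvents()` sorts
descending with alphabetical tie-breaks (ties are flagged).
`property_correlations()` reports Spearman rank correlation as the primary
statistic -- the claims of interest are monotone trends, not linear laws --
with Pearson alongside, and emits no significance claim by default: with
nine solvents a permutation $p$-value (available via `n_perm`) is honest
about how weak such evidence is. The bundled solvent property table
(relative permittivity, dipole moment, density, carbon count for the nine
polar aprotic solvents) ships as editable handbook-style reference data,
not ground truth.

## Synthetic data and what passing tests show

The generators in `toy_crystal()`, `layered_frames()`, `sideratio_table()`
and `adsorption_config()` produce every input class the pipeline consumes,
bit-identically reproducible under a fixed seed, with their ground truth
recorded (planted layer centers and overlap fractions, planted slopes,
designed interaction-energy regimes). They emulate the *structure* of real
inputs -- periodic crystals, layered interfacial trajectories with
prescribed density peaks near a surface edge at ~22.7 Å, linear
side-ratio--volume data -- but not their physics: no equilibrated liquid
structure, no realistic solvent conformers, no force-field realism beyond
LJ/Coulomb toys. Passing tests therefore demonstrate that the analysis
stages are *correct* (they recover what was planted, match independent
oracles, and satisfy the model's identities), not that the simplified
energetics would reproduce measured adsorption energetics of a real
crystal--solvent system.

Problem sizes used by the test suite were chosen as the smallest that make
each statistical check well-posed: $10^6$ Monte-Carlo samples for the
facet-area oracle, 100 random clusters of up to 50 atoms for the pair-sum
oracle, 100 seeded trials with 4000-atom layers for peak recovery, and 500
seeds for slope-recovery bias.

## Known limitations

* Laue coverage excludes trigonal/hexagonal classes (errors are explicit).
* The toy attachment-energy path requires an axis-aligned face normal;
  general oblique slicing is not implemented.
* Electrostatics of periodic systems are minimum-image truncated, not
  Ewald-summed; absolute energies of charged periodic systems are
  convention-dependent and only energy differences with identical settings
  are meaningful.
* The interface builder produces unrelaxed geometries; any property that
  depends on an equilibrated interfacial structure requires an external
  engine (the emitted protocol block documents the intended settings:
  298.15 K, NVT, NHL thermostat, 15.5 Å cutoff, 500 ps at 1 fs).
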