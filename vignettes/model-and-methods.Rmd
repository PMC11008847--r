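---
title: "The deformable-polygon model of epithelial apical-basal architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The deformable-polygon model of epithelial apical-basal architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(epideform)
```

## The model

`epideform` simulates cross-sections of cultured epithelial monolayers in
the apical-basal (XZ) plane. Each cell cortex is a closed polyline of
~100 nodes; the substrate is a fixed, rigid line of nodes on the X axis.
Node positions follow overdamped dynamics, `F = beta * v`, integrated with
an explicit Euler step (`dt = 1`, `beta = 1`); 750 timesteps correspond to
one hour in culture.

The net force on a node is the sum of five contributions:

* **Internal regulation of size and shape.** Each cell carries the energy
  `E = 1/2 k_A (A - A0)^2 + 1/2 k_L L^2` (area `A`, perimeter `L`); nodes
  feel its negative gradient. Alone, this relaxes a cell to a circle of
  area `A* = A0 - 2*pi*k_L/k_A`, which the test suite verifies against the
  simulation.
* **Cell-substrate adhesion.** Linear springs (strength `gamma_cs`, rest
  length `l_cs`) between cell and substrate nodes closer than `d_cs`,
  under mutual-nearest exclusivity: a substrate node binds only its
  nearest cell node and vice versa. Bonds are stateless and recomputed
  every step, so a spring "breaks" by leaving the interaction range.
* **Cell-cell adhesion and repulsion.** Springs between all node pairs of
  different cells closer than `d_cc` (no exclusivity). Above the rest
  length `l_cc` the strength is `gamma_cc`; below it a constant repulsive
  strength `R_cc` replaces `gamma_cc`, so repulsion is independent of
  adhesion and arbitrarily small adhesion strengths can be studied.
* **Gravity.** A small constant `(0, -C_G)` on every node of cells that
  have no path to the substrate through the current bond network (cells
  and substrate as graph vertices, bonds as edges). Gravity is orders of
  magnitude weaker than the other forces and is dropped once a cell rests
  on, or is connected to, the substrate.
* **Active spreading.** Substrate adhesion alone leaves a plated cell
  round; spreading in culture requires active protrusion. Once 10% of a
  cell's nodes hold substrate bonds, a constant force of magnitude `C_s`,
  pointing 45 degrees outward and below horizontal, loads the node just
  outside the bonded run on each side. Contact inhibition acts per side:
  a side in contact with a neighbour receives nothing while the other
  side continues.

Two further processes shape the dynamics. A **feedback** between the two
adhesion systems acts whenever a cell holds at least one attractive
cell-cell bond: `gamma_cc` is multiplied by `1 + 0.03 * N_sub` (with
`N_sub` the previous step's substrate-bond count), `gamma_cs` by 1.5 and
the search range `d_cc` by 1.2, letting touching cells grow their contacts
and find neighbours at increased range. **Cortical remodeling** keeps the
discretization uniform: edges longer than twice the construction-time
reference spacing gain a midpoint node; for edges shorter than half of it,
the endpoint closer to its other neighbour is removed. The reference
spacing is deliberately fixed at construction; an instantaneous mean would
drift as the cell stretches.

**Division** doubles the preferred area linearly over the final hour of a
cell's cycle while setting that cell's `gamma_cc` to zero (repulsion stays
on — it is adhesion-independent). The polygon then splits along the chord
between its topmost and bottommost nodes (planar division), and repeated
remodeling populates the cytokinetic plane. Daughters restart at age zero
with the base preferred area. Initial cycle lengths are drawn uniformly
from [0, 4] hours.

## Parameters

All simulations run in the non-dimensional unit system in which the
preferred cross-sectional area is 1 (about 100 um^2 for an MDCK cell, so
one length unit is 10 um) and the area stiffness is 1. Defaults
(`model_params()`): `k_L = 5e-4`, `gamma_cc = 1e-3` (0.2 N/m),
`R_cc = 0.05`, `gamma_cs = 0.1` (20 N/m), `d_cc = 0.16`, `d_cs = 0.1`,
`l_cc = l_cs = 5e-3`, `C_s = 8e-3`, `C_G = 1e-3`. The drag coefficient has
no published value; it only rescales time jointly with `dt`, so `beta = 1`
and the clock is anchored by the 750-steps-per-hour calibration instead.
The spreading force magnitude can be constant, linear in
`gamma_cs/gamma_cs_ref`, or that ratio to the power 0.2 (the nonlinear
model that best matches observed spreading on weak substrates).

Numerical notes: with these values and `dt = 1` the stiffest interactions
(effective substrate springs at `1.5 * gamma_cs = 0.15`) are far below the
explicit-Euler stability bound, and per-step node displacements stay below
0.05 length units in all shipped scenarios (asserted in the tests).
Degenerate geometry is handled conservatively: zero-length edges
contribute zero tangent (with a warning), coincident bonded nodes exert no
force, and a division whose top and bottom nodes coincide is aborted.

## Scenarios and design choices

The package ships five scenarios (see `scenario_config()`). Choices the
source material left open, and how they were fixed:

* **Placement in the confinement scenario.** `four_cell_confined` places
  cells evenly across the available substrate and seeds them essentially
  at the substrate surface (gap 0.05). Packing all cells at the centre
  instead leaves every cell contact-inhibited from the first step; they
  never spread, and even the sparsest layers classify Intermediate.
  Even placement expresses what the scenario varies — the amount of basal
  substrate available to a fixed number of cells. Near-substrate seeding
  makes every cell engage the substrate at once; cells dropped from a
  height while already within cell-cell interaction range can otherwise
  be left dangling: the first substrate bond anywhere in the contact
  network switches gravity off for all of its members.
* **Plating scenarios.** `single_cell_spreading`, `two_cell_plating` and
  `three_cell_division` drop round cells from 0.4 length units with
  neighbouring cortices just outside `d_cc`, reproducing plating
  behaviour (fall, attach, spread, meet).
* **Division timing.** In `three_cell_division` the sampled U[0, 4] h
  cycles are offset by a 6 h settling period so that the colony is an
  established spread layer before the central cell (which receives the
  shortest cycle) divides. Only the central cell divides in this
  scenario; daughters leave the cycle.
* **Densification grid.** Sweeps default to 12 substrate lengths
  `L = sqrt(160/a)` for target densities `a` from 1 to 9 Arb. Sweep
  summaries average the frames of the final two culture hours of each
  24 h run; single-frame summaries flicker by one or two bonds.
* **Contact sides.** For per-side contact inhibition, a bond partner whose
  centroid lies at lower x sets the left flag, else the right flag.
* **Bond symmetry.** The printed cell-cell force law is per-cell, which
  after per-cell feedback would violate force balance between two cells in
  different feedback states. Each bond instead uses the smaller of the two
  cells' effective `gamma_cc`: forces stay equal and opposite, and a
  dividing cell's ceased adhesion silences its bonds on both ends. The
  matching range of a pair is the larger of the two cells' effective
  `d_cc`.
* **Evaluation order.** Within a step: divisions due, remodeling, division
  program, bond matching (ranges from the previous step's contact flags),
  effective parameters (this step's contacts, previous step's `N_sub`),
  forces, Euler move.

## Measurements

Per-cell connection fractions `f_cs` and `f_cc` (fraction of nodes holding
substrate / attractive cell-cell bonds) proxy the substrate and lateral
interface lengths. Layer density is the cell count over the occupied
substrate span (outermost bonded nodes), scaled by the fixed convention
`Arb = (cells/mm)^2 / 1000`, anchored so that four cells on 47.8 um give
7.0 Arb = 7.0e3 cells/mm^2. A layer is Intermediate when the interior-cell
mean `f_cc` reaches 0.10 (with ~100 nodes, more than one connection per
cell); edge cells are excluded from classification but counted in density.
The apical surface is the longest polyline arc of nodes holding no bonds
of either kind; the basal surface is the contiguous substrate-bonded run;
the shape index is `sqrt(4*pi/circularity)`, which maps the observed
circularity plateau of 0.84 to 3.87 and the vertex-model jamming point to
3.81. (The ratio's printed form without the square root is dimensionally
inconsistent with both of those values; the square-root reading reproduces
them.)

## What the simulations show, and known limitations

With standard parameters the densification sweep reproduces the published
qualitative structure: substrate connections fall and cell-cell
connections rise monotonically with density; layers are Immature at low
density and Intermediate at high density, with the 10% crossing at
2.6e3 cells/mm^2 here (published simulations: 3.1e3), shifting upward to
4.5e3 when cell-cell adhesion is reduced a hundredfold (published: 3.6e3
at the same reduction — same direction, stronger shift here). Intermediate
architecture still forms at 4 N/m substrate adhesion under nonlinear and
constant spreading and at 20% of reference under linear scaling,
consistent with the published bounds (4 N/m and 50%).

One published simulated feature is not reproduced: the apical-to-basal
surface-length ratio here declines from the sparsest layers onward
(1.16 at 1 Arb to ~0.8 beyond 5 Arb) instead of rising to a peak near
7 Arb. The adhesion feedback zips neighbouring cortices into tall lateral
walls once contact forms, and the exclusion-based apical measure then
loses most of the dome arc. Under a hundredfold reduced `gamma_cc` the
rise-then-decline shape does appear (peak near 4 Arb), which points at the
lateral-wall growth rate, not the measurement, as the divergent element.
The affected check is kept failing in the test suite rather than loosened.

The generator emulates small colonies (1-4 cells, one division) over 24
culture hours. It does not emulate: three-dimensional packing (densities
are a scaled linear measure, not directly comparable to cells/mm^2 in
culture), apical flattening and Mature architecture (no apical-basal
molecular asymmetry in the model), cell extrusion or death, or volume
exclusion beyond short-range node repulsion — crowded cortices can
interpenetrate, which bounds the usable density range near the top of the
swept interval. Passing tests therefore support the crowding mechanism of
the Immature-to-Intermediate transition, not quantitative prediction of
cultured-layer measurements.

## Problem sizes

The shipped test-and-acceptance configuration uses the full study
conditions: 100-node cells, 24 h-equivalent (18,000-step) runs, 12-point
densification sweeps and 5-6-point adhesion sweeps. The whole suite runs
in under ten minutes on one CPU; a single 24 h four-cell run takes a few
seconds to a quarter of a minute depending on density.
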