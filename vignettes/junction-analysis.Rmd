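---
title: "Holliday junction sequence, geometry and ion-binding analysis with hjkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holliday junction sequence, geometry and ion-binding analysis with hjkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hjkit)
```

`hjkit` analyzes four-way (Holliday) DNA junctions of the kind used as the
core motif of self-assembling 3D DNA crystals. This vignette documents the
models behind each module, the conventions the package fixes where several
choices were possible, and what the synthetic validation data do and do not
establish about real structures.

## The strand/arm convention

Everything downstream depends on one piece of bookkeeping, fixed once:

* Arms 1–4 are indexed cyclically going around the junction (arm 5 ≡ arm 1).
* Strand *i* runs 5′→3′ through arm *i* into arm *i*+1. Arm *i* is therefore
  the antiparallel duplex of strand *i* (entering the junction) and strand
  *i*−1 (leaving it).
* The branch-point base pair of arm *i* is written as the base
  *b<sub>i</sub>* on strand *i* (the arm's *reference strand*); its partner
  on strand *i*−1 is comp(*b<sub>i</sub>*) by Watson–Crick complementarity.

A branch-point assignment is the quartet (*b₁*, *b₂*, *b₃*, *b₄*), so there
are 4⁴ = 256 assignments.

## Branch migration and the 36 immobile classes

One step of branch migration along the (1,3) axis shrinks arms 1 and 3 by
one pair and grows arms 2 and 4. `migrates_one_step()` models the step
explicitly: it breaks the two branch pairs on the shrinking arms, freeing
*b₁* (strand 1), comp(*b₁*) (strand 4), *b₃* (strand 3) and comp(*b₃*)
(strand 2), and re-pairs each freed base with the freed base of the strand
it meets in the growing arm: arm 2 (strands 1 and 2) gains *b₁*:comp(*b₃*),
arm 4 gains *b₃*:comp(*b₁*). The step is allowed iff both new pairs are
Watson–Crick. Algebraically that reduces to *b₁* = *b₃* (and *b₂* = *b₄*
for the other axis), but the package computes the re-pairing directly; the
reduction is verified against it over all 256 × 2 cases in the test suite
rather than assumed.

A junction is *immobile* when neither axis permits a step: *b₁* ≠ *b₃* and
*b₂* ≠ *b₄*, giving 4·3·4·3 = 144 immobile assignments (the suite also
cross-checks this by inclusion–exclusion, 256 − 64 − 64 + 16). Relabeling
the strands cyclically rotates the quartet, so physically identical
junctions are collapsed into orbits under rotation:

* Equivalence uses cyclic rotations only — not reflections or strand-sense
  reversal. Reflections would identify sequence-distinct junctions and
  change the count; rotation is the relabeling freedom actually present in
  the four-strand object.
* Every immobile orbit has size 4 (a period-2 orbit would need *b₁* = *b₃*,
  which immobility forbids), so there are 144/4 = 36 classes.
* The canonical member of each class is its lexicographic minimum under
  A < C < G < T; classes are reported in canonical order and labelled
  C01–C36 by default. The conventional J1…J36 naming is a figure-derived
  convention, so it is supported only through a user-supplied label vector.
* Classes are stacking-isomer-agnostic: which of the two stacking isomers a
  sequence adopts is a structural property, not a sequence-combinatorial
  one.

`realize_sequences()` turns a class into four concrete strands (each
spanning two adjacent arms) with seeded or user-supplied stems; the
branch-point quartet is re-read from the strands as a round-trip check.

## Signed J-twist geometry

The analysis assumes the stacked-X conformation: the four arms coaxially
stack pairwise into two quasi-continuous helices crossing at the branch
point. In the package's idealized model each stack pairs *opposing* arms
({1,3} and {2,4}); declaring non-opposite stacks is accepted but flagged.

* **Pair reference point.** The midpoint of the two C1′ atoms of a base
  pair. This is robust, parameter-free, and adequate for B-form stacks.
* **Axis fit.** The total-least-squares line (first principal direction of
  the centered points) through the ordered pair points of the stack's two
  arms. The fit residual (RMS point-to-line distance) is reported.
* **Axis orientation.** Each stack's direction points away from the branch
  point toward the distal end of the arm listed first in the stack
  declaration. This fixes the sign of the dot product so angles are
  comparable across frames.
* **Angle.** arccos of the dot product of the two unit axis directions,
  in [0°, 180°).
* **Handedness.** A reference vector is taken from the centroid of the
  junction-proximal-pair C1′ atoms of stack 1 to that of stack 2 and
  orthogonalized against both axis directions. If its angle to
  axis₁ × axis₂ is below 90° the junction is right-handed, above 90°
  left-handed, and left-handed angles are normalized by −1. The construction
  is a package convention (several perpendicular-vector constructions are
  defensible); it was chosen because it flips sign together with the cross
  product when the two stacks are swapped, which makes the *signed* angle
  independent of stack ordering — a property the test suite asserts, along
  with exact sign flip under mirror operations and invariance under proper
  rigid motions. An exact 90° tie is classified right-handed with a warning
  (a measure-zero case needing a deterministic rule).
* **σ convention.** Angle (and incidence) summaries use the sample standard
  deviation (n − 1): the junction groups being summarized are small samples.

Per-frame failures in `jtwist_series()` are recorded with the frame index
and the series continues, so a single degenerate frame does not void a
trajectory.

## Ion bridging at the branch point

The two conserved branch-point sites sit at the two strand-exchange points,
on opposite sides of the junction. Site *Pos1* is anchored at the crossover
phosphate of strand 1 (the phosphate of the residue immediately 3′ of the
branch residue) and *Pos2* at strand 3's; each site comprises that
phosphate's anionic oxygens (OP1/OP2) plus the hydrogen-bond-acceptor base
atoms of the two junction-proximal base pairs of the arms the strand
connects. The acceptor table is: A — N7, N3; G — N7, O6, N3; C — O2, N3;
T — O2, O4.

A bridging event requires one ion simultaneously within the cutoff of at
least one site phosphate oxygen **and** one site base acceptor of the same
site. The default cutoff is 3.6 Å — a typical first-shell K⁺/Na⁺–O/N
coordination distance — and is purely distance-based, with no angular term;
the same rule and default apply to divalent species. An ion satisfying both
sites in a frame is assigned to the nearer site and counted once per frame.
The minor-groove ion cluster sometimes seen near *Pos2* in crystals is not
modelled: it makes no junction contacts. Incidence pools all frames of a
trajectory with equal weight; replicas, if analyzed jointly, should simply
be concatenated.

Cacodylate deserves a note: crystallization buffers often place a
cacodylate arsenic where simulations place K⁺. The reader therefore treats
cacodylate as a single ion-like site at its arsenic atom, so occupancy
analysis works uniformly across crystal and simulation inputs.

## Lattice cavities and cell statistics

Cavity volumes are idealized solid prisms — triangular,
(√3/4)·e²·h, and hexagonal, (3√3/2)·e²·h — with no van der Waals
subtraction of the DNA walls; this is exactly the model under which the
well-known ~24 nm³ (edge 3 nm, height 6.1 nm) and ~639 nm³ (edge 6.4 nm,
height 6.0 nm) trigonal-lattice values arise, and their ratio is the
familiar ~27-fold cavity-size increase. No default prism parameters are
shipped for other lattices; they are user-supplied specs.
`cell_statistics()` reports per-axis mean, sample σ (absent for a single
cell) and range for any group of unit cells, e.g. grouped by space group.

## The synthetic generator

`build_junction()` places two straight, rigid, idealized B-form stacks
(constant rise 3.38 Å/bp and twist 34.3°/bp, planar pseudo-pairs) crossing
at the requested interduplex angle, with the two axes in parallel planes
10 Å apart. The canonical construction is right-handed under the package
convention — the branch-point reference vector and the axis cross product
both point from stack 1 toward stack 2 — and left-handed structures are
produced by mirroring through a coordinate plane, an exact handedness flip.
Each residue carries a minimal atom set (C1′, P/OP1/OP2 except at 5′
termini, and the base's acceptor atoms); C1′ atoms are placed antipodally
about the pair center so pair midpoints lie exactly on the construction
axis and the zero-noise axis fit is exact. Atom placement radii were chosen
once so that the crossover phosphate oxygens sit ~5.4 Å from the adjacent
base acceptors, putting the planted-ion bridge midpoint (~2.7 Å per
contact) well inside the 3.6 Å cutoff even under the default thermal-noise
levels.

`build_trajectory()` makes seeded, bit-reproducible frames with isotropic
Gaussian noise on the DNA atoms. Bound frames place the ion at the midpoint
of a site phosphate oxygen and base acceptor *in that frame's coordinates*
(optionally radially offset); unbound frames park it > 10 Å from both
sites. Ground truth (constructed angle, handedness, bound-frame set) is
attached to the object and written as a JSON sidecar by
`write_synth_bundle()`, so tests never re-derive truth from the analysis
under test.

What the generator does *not* emulate: sequence-dependent helical
structure, backbone chemistry beyond the phosphate group, solvent, base
pair breathing, stacking-isomer exchange, or real ion diffusion. Passing
the synthetic suites therefore establishes that the geometric and
ion-detection machinery is correct under its stated conventions — not that
those conventions numerically match any particular third-party angle
definition on experimental coordinates (axis definitions can differ by a
few degrees on real, bent helices).

## Problem sizes and numerical choices

The shipped tests use 8-bp arms (4-bp for some I/O fixtures), trajectories
of 10–100 frames, a 6-angle × 2-handedness recovery grid at zero noise
(tolerance 2°), thermal noise σ = 0.3 Å for statistical checks (median
within 3°), and rigid-motion invariance at 1e−6°. These sizes give
well-conditioned fits while keeping the whole suite fast to run anywhere.
PDB round trips are compared at 1e−3 Å (the format's coordinate
precision). Degenerate inputs are errors, not silent results: empty files,
< 4 base pairs per stack, zero-extent stacks, zero-frame incidence, empty
summary inputs.

## Analyzing real structures

No test depends on network data, but deposited junction crystals and
simulation snapshots can be analyzed directly:

```r
# s <- read_hj_structure("6X8C.pdb")            # or .cif
# s <- annotate_junction(s, strands = data.frame(
#        chain = c("A","B","C","D"),
#        first = ..., last = ..., branch = ...),
#        stacks = list(c(1,3), c(2,4)))
# jtwist(s); branch_point_sites(s); s$cell
```

The strand/stack declaration must be supplied by the user — which arms
coaxially stack in a given deposited structure is a modelling decision that
cannot be read from the coordinate file — and no numeric equality with
published per-structure values is asserted by the package.

## Interfaces

All functionality is exposed as R functions (this is an analysis library in
the bio3d/vegan mould, so functions plus this vignette are the interface;
no shell entry point is shipped). FASTA export of classes and strand sets,
TSV class tables, JSON junction specs/ground truth, and tidy data frames
from `jtwist_series()`, `detect_ion_events()` and `site_occupancy_table()`
cover file-level interchange.
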