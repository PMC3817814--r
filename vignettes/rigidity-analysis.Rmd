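---
title: "Rigidity analysis of assemblies and crystal lattices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigidity analysis of assemblies and crystal lattices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidcryst)
```

This vignette is the package's own account of the science it implements:
the mechanical model and its assumptions, the parameters that matter, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the places where the design was genuinely open.

## The mechanical model

A molecule is abstracted as a *body-bar-hinge framework*. A **body** is a
set of atoms whose pairwise distances are fixed by covalent geometry:
`infer_covalent_bonds()` detects bonds by distance (covalent radii sum +
0.4 Å, radii after Cordero et al. 2008) and marks a bond *locked* when its
torsion is not a degree of freedom — peptide/amide C–N bonds, ring bonds,
bonds to terminal atoms, residue-template partial double bonds (carboxyl,
amide, guanidinium), and disulfides. Contracting locked bonds yields the
bodies; each remaining rotatable bond between two bodies is a **hinge**.
The two hinge atoms belong to both incident bodies; this shared-atom
convention is applied consistently, so ethane decomposes into two
clusters of five atoms each (methyl group plus the two shared carbons)
and cluster sizes at interfaces add the shared atoms to every incident
cluster.

Constraints enter a multigraph on the bodies as bars: a hinge leaves
exactly one relative degree of freedom, hence 5 bars; a hydrogen bond is
likewise modeled at 5 bars; a hydrophobic tether at 2, reflecting its
softer, slippier character. These multiplicities follow the convention of
the established rigidity-analysis software lineage; since published
cluster tables never state them, they are exposed as a first-class
`bar_policy()` object rather than constants, and the hydrophobic count (2
vs 3 in some versions of comparable software) is an explicit sensitivity
axis. Parallel bars between one body pair cap at 6, which is the most
that can ever be independent.

## The (6,6) pebble game

A framework of V free bodies has 6V degrees of freedom, 6 of them trivial.
Tay's theorem characterizes generic body-bar rigidity combinatorially:
a bar set is independent iff every subset S of bodies spans at most
6|S| − 6 bars ((6,6)-sparsity, equivalently six edge-disjoint spanning
trees for tight graphs). `pebble_game()` computes the rank of this count
matroid: every body starts with 6 pebbles; a bar (u, v) is accepted iff 7
pebbles can be gathered on {u, v} by reversing search paths; accepted
bars are oriented and consume a pebble. The invariant
`pebbles(v) + outdegree(v) = 6` holds after every move, and the accepted
count is the matroid rank regardless of processing order (edges are
nevertheless processed in a deterministic sorted order so runs are
byte-reproducible).

Rigid components are recovered through the matroid, not through geometry:
two adjacent bodies lie in a common (6,6)-tight set iff a 7th pebble
cannot be gathered on the pair. Because tight sets sharing a vertex union
to a tight set, this relation is transitive, and a union-find pass over
the edges partitions the bodies into maximal rigid components; atoms of a
component's bodies form the rigid cluster. `internal_dof()` reports
`6V − 6 − rank` per connected component, with the 6 relative rigid-body
motions per extra component reported separately.

`oracle_rank()` provides the independent check used throughout the test
suite: it re-derives the rank directly from the sparsity definition,
verifying `bars(S) <= 6|S| − 6` over all vertex subsets on every
insertion. Full enumeration of all bar subsets is unnecessary because
(6,6)-sparse sets form a matroid, where greedy insertion is exact; as a
guard against an implementation error in that very assumption, the greedy
pass is repeated over 20 shuffled insertion orders and the maximum taken.
The oracle deliberately shares no code with the pebble game and is
restricted to V ≤ 6, ≤ 20 bars.

## Interactions

Hydrogen bonds: donors are N/O/S atoms with a bonded hydrogen, acceptors
are N/O/S; geometric gates H···A ≤ 2.6 Å, D···A ≤ 3.6 Å, ∠DHA ≥ 90°, with
acceptors 1-2 or 1-3 bonded to the donor excluded. Candidates are scored
with a Mayo-style well

\[ E = V_0\left[5\left(\tfrac{R_0}{R}\right)^{12} -
     6\left(\tfrac{R_0}{R}\right)^{10}\right]\cos^4\theta , \]

\(V_0 = 8\) kcal/mol, \(R_0 = 2.8\) Å, R the donor–acceptor distance,
θ the D–H–A angle, and kept at `energy ≤ −1.0` kcal/mol. The −1.0 default
is a package choice: comparable software exposes the same dial without a
canonical published value, and reported cluster sizes for real crystals
are sensitive to it — which is why `sensitivity_report()` sweeps the
cutoff (and the hydrophobic tolerance) rather than trusting any single
point. Hydrogen placement is a genuine upstream degree of freedom with
documented consequences (a handful of rotamer-dependent hydrogen bonds
can change a trimer's decomposition from asymmetric to symmetric); the
package therefore accepts pre-protonated input, ships only a deliberately
naive `place_hydrogens()` (1.0 Å, opposite the mean neighbor direction,
seeded fallback), and leaves serious placement to dedicated external
programs. `apply_curation()` exists precisely to test such
placement hypotheses by hand-editing individual bonds.

Hydrophobic contacts: C/S pairs from different residues within the van
der Waals sum (Bondi radii) + 0.25 Å, excluding covalently near pairs.

## Symmetry and assembly building

The space-group registry is generated, not tabulated: a plain-text file
ships one row per group (Hermann–Mauguin symbol, ITC number, crystal
system, centering, generator triplets, published order), and
`space_group()` parses the triplets and computes the closure under
composition modulo lattice translations. The published order serves only
as a consistency check; the Sohncke flag (65 groups) is computed from the
closure determinants, and `sym_classify()` distinguishes identity /
translation / rotation / screw rotation / improper by the determinant and
the intrinsic translation \(\tfrac1n\sum_k R^k t\) along the rotation
axis. Fractional translations are held as multiples of 1/24 (exact for
all crystallographic screw/glide components); rhombohedral groups are
stored in the hexagonal setting, matching PDB files, with `H`-symbol
aliases mapped to the `R` symbols. Orthogonalization follows the PDB
convention (a along x, b in the xy-plane) with the closed-form volume
discriminant rejected when non-positive. Tolerances: 1e-6 for
determinant/orthogonality checks on operators, 1e-3/1e-2 when matching
parsed SMTRY records (PDB remarks print 6/5 decimals).

Three builders generate assemblies. Biological assemblies apply REMARK
350 BIOMT matrices (cartesian Å frame) to the targeted chains, with
optional transform subsets for partial assemblies. Unit cells apply the
registry closure in fractional coordinates. Supercells translate the cell
by integer combinations of the cell vectors. One design question deserved
care: some deposited files describe crystal generation loosely in terms
of REMARK 350, but BIOMT encodes the *biological* assembly, which need
not tile the crystal. The builder therefore derives crystal symmetry from
CRYST1's space-group symbol plus the registry closure, and uses REMARK
290 SMTRY records only as a cross-check (warning on mismatch). Copies are
not wrapped into the unit box by default — finite, explicit-geometry
crystals — and atoms on special positions are not deduplicated, keeping
the count invariant `atoms = |ops| × AU` exact. Every copy carries a
`unit_label` (stored in the segment-identifier columns so it survives
writing) and fresh chain labels from the documented cycle A–Z, a–z, 0–9,
then two-character labels. The PDB writer enforces the format's 99,999-
serial capacity with three policies (error / wrap / hybrid-36 encoding).

Note that published per-structure narratives occasionally state unit-cell
asymmetric-unit counts that differ from the space-group order (e.g. a
6-operation group described with 2 AU per cell); the builder always
follows the group order, which is the only self-consistent reading.

## Cluster tables and behavior classification

`cluster_table()` histograms cluster sizes per level; `label_clusters()`
marks sizes ≥ 20 atoms as significant (smaller clusters typically belong
to flexible regions) and the largest size as dominant when it is unique
and ≥ 3× the runner-up significant size. Both thresholds are package
choices — the source analyses state that such thresholds exist without
printing values (a 710-atom cluster over ≤ 19-atom background is
described as dominant, which a 20/3.0 setting reproduces) — and both are
arguments everywhere they matter.

Cross-level comparison is made precise by `scaling_deviation()`: growing
a structure by factor n without new inter-unit coupling must multiply
every count by n, so *aggregation* is operationalized as `merged_mass >
0` — atoms in derived clusters larger than anything at the base level.
`classify_behavior()` evaluates seven ordered rules on the AU / cell /
2x1x1 / 2x2x1 tables (cell compared against AU, crystals against the
cell): aggregation everywhere (1); only at the cell, with a dominant cell
cluster (2); nowhere (3); at the cell and 2x2x1 but not 2x1x1 (4); equal
AU/cell dominant with crystal-level collapse (5); cell-spanning without
further aggregation (6); otherwise unclassified (7). The prose behind
cases 2, 5 and 6 overlaps for some patterns; rule order is the
documented tie-break, and case 2 is distinguished from case 6 by
requiring a dominant (not merely significant) cell cluster.

## The synthetic-data generator

`make_molecule()` produces methane, ethane, n-alkanes and a formyl-capped
polyglycine backbone with ideal covalent geometry (C–H 1.09 Å, C–C 1.54
Å, planar peptide units), each carrying its designed body/hinge/DOF
counts. For the backbone, n peptide planes joined through alpha carbons
give 2n − 1 bodies and 2n − 2 hinges (phi/psi); for n = 2 this is the
textbook three-bodies-two-hinges fragment.

`make_toy_crystal()` emits complete PDB files (CRYST1, REMARK 290
consistent with the registry closure, an identity REMARK 350 assembly)
with two motifs whose interface behavior is designed, not tuned:

* **rod** — a rigid O=C–N–H unit along +x. With cell edge `a = 5.64` Å
  the +a image's acceptor sits exactly 2.0 Å from the donor hydrogen on
  the bond axis, giving one designed inter-cell hydrogen bond
  (E ≈ −6.5 kcal/mol) and nothing else; with 30 Å edges nothing
  interacts, so counts scale exactly 1:2:4:8 across AU/cell/2x1x1/2x2x1
  in a 2-operation group and the classifier must return case 3.
* **ring** — cyclopropane stacked on a 2₁ screw axis. At `a = 3.6,
  b = 7.0` every adjacent pair (screw partner, a- and b-translates)
  shares ≥ 3 carbon contacts = 6 bars, so all copies fuse rigidly at
  every level and the classifier must return case 1.

What the generator does *not* emulate: side-chain rotamer diversity,
alternate conformers, solvent, special-position overlaps, and the dense
many-body interaction networks of real proteins. Passing the synthetic
suite therefore validates the machinery — symmetry expansion, constraint
counting, matroid rank, aggregation logic — but says nothing about
whether a particular real crystal's published cluster sizes will be
reproduced: those depend on hydrogen placement and on interaction
cutoffs that published tables do not pin down, which is why real
structures are tracked through `sensitivity_report()` as benchmarks
rather than asserted at a point.

## Numerical choices and degenerate inputs

* Fractional translations snapped to 1/24; closure aborts past order 192
  (the largest space group), which catches corrupt generator rows.
* Altloc duplicates resolved to the highest-occupancy conformer, ties to
  the first encountered; water HETATMs dropped by default.
* Malformed CRYST1 degrades to "no crystal" with a warning; a file with
  no atoms is a hard error; an atom with more than 8 inferred bonds is
  rejected as corrupt input.
* A rotatable bond closing a ring of locked bonds is reclassified locked
  (logged); single-atom bodies with one incident rotatable bond merge
  into their neighbor, since a lone atom carries no torsion.
* Edges are processed in sorted order and all builders iterate operations
  and cells deterministically, so two runs with one configuration are
  byte-identical.

## Problem sizes

The shipped tests run entirely on generated inputs: molecules of 5–23
atoms, toy crystals up to 8 copies of a 4–9-atom motif (72 atoms), random
body-bar multigraphs with up to 5 bodies and 14 bars (200 seeds for the
oracle comparison, 50 edge-order shuffles), and the full 230-group
registry closure. These sizes were chosen so every expected value is
checkable by hand or by the independent oracle; the engine itself has no
such limits (graph search is linear per pebble search, and the dense
directed-bar matrix is the only structure that would want sparsifying
for very large assemblies).

## Known limitations

* Rigidity is generic/combinatorial: geometric special positions that
  create coincidental dependencies are not detected.
* The crystal model is a finite block; truly periodic rigidity (torus
  boundary conditions) is a different computation and out of scope.
* The hydrogen placer is a fixture-grade fallback, not a replacement for
  a dedicated placement program.
* Interaction detection treats all N/O/S donors/acceptors uniformly; no
  salt-bridge or aromatic-stacking special cases beyond the energy model.
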