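---
title: "Elastic-network perturbation analysis of symmetric channel gating"
author: "PerturbANM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network perturbation analysis of symmetric channel gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PerturbANM)
```

## The model and its assumptions

`PerturbANM` treats a protein at Cα resolution as a mass-and-spring
network. Every residue is a node; every pair of residues closer than a
cutoff is joined by a harmonic spring relaxed at the observed distance:

$$V = \tfrac12 \sum_{(i,j)\,\in\,\text{contacts}} \gamma_{ij}\,
      \bigl(r_{ij} - r_{ij}^{0}\bigr)^2 .$$

This anisotropic network model (ANM) assumes the input structure is an
equilibrium conformation, that fluctuations around it are harmonic, and
that spring stiffness needs only two classes: backbone-consecutive
("covalent") pairs and everything else. Those are strong assumptions,
but ENMs are famously robust to them — soft (low-frequency) modes of the
Hessian are dominated by the topology of the contact map, not by the
details of the force field, which is why the approach tolerates
homology-model-quality coordinates.

The Hessian $H$ of $V$ at equilibrium is assembled per contact: with
separation vector $d$ and distance $r$, the off-diagonal $3\times3$
block is $H_{ij} = -(\gamma_{ij}/r^2)\, d\,d^{\mathsf T}$ and diagonal
blocks accumulate the negatives, so every block row sums to zero
(translation invariance). For one rigid connected body exactly six
eigenvalues vanish (three translations, three rotations). The package
treats this as a *contract*: `diagonalizeHessian()` raises a classed
error whenever the numerical null count differs from six, because a
silently wrong rank corrupts every downstream quantity. Nullness is
judged relative to the stiffest mode, $\lambda < 10^{-8}\lambda_{\max}$.

Linear response theory (LRT) supplies the perturbation step. The
equilibrium covariance of the network is the Moore–Penrose pseudoinverse
$C = \sum_{k>6} \lambda_k^{-1} v_k v_k^{\mathsf T}$ (kept in factored
form), and the expected displacement under an external force $F$ is

$$\Delta r = \beta\, C\, F .$$

The physical picture: ligand (un)binding is not modeled as a particle
but as a force applied to the binding-pocket residues, and the
*pre-existing* equilibrium fluctuations of the receptor determine how
that force propagates. The output is qualitative — the magnitudes carry
arbitrary units and only ratios between residues are interpretable. All
package outputs are labeled accordingly, and the screen below is
normalized to be scale-free.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `cutoff` | 10 | Å | standard ANM contact radius; strict `<` at the boundary ("smaller than") |
| `gammaCovalent` | 82 | RT/Å² | backbone peptide-bond stiffness |
| `gammaNoncovalent` | 3.166 | RT/Å² | Miyazawa–Jernigan average for noncovalent interactions |
| `beta` | 1 | arbitrary | force constant; responses are shape-only, so the default is a pure sign convention (+1 = pocket-opening; a negative value mimics the opposite event) |
| `threshold` (degeneracy) | 0.95 | – | minimum pairwise quarter Pearson correlation, strict `>` |
| `deltaThreshold` | 0.1 | fraction of peak baseline displacement | switch-off significance level |
| `minResidues` | 15 | residues per subunit | a removal must reshape the field this broadly in *every* subunit |
| `tolRel` (null modes) | 1e-8 | relative to λmax | numerical rank decision |

"Covalent" means *consecutive residue numbers in the same chain*; a
numbering gap is taken as missing residues, hence no peptide bond, and
cross-chain pairs are never covalent. Covalent springs are kept
regardless of distance and are excluded from switch-off: removing a
backbone bond would model chain scission, not contact loss.

Temperature never appears as a parameter — it is absorbed into the RT
unit of the spring constants, consistent with the arbitrary-units
character of the response.

### Force conventions

For the binding pocket, each targeted residue receives a *unit* vector
pointing from the pseudo-ligand center towards its Cα; equal per-residue
magnitudes reflect that atomistic details of binding are unknown. For a
tetramer the same pocket is forced in all four chains, each with its own
(symmetry-related) center.

For the voltage mimic, the field axis is the membrane normal (ẑ by
default) and each formally charged residue (ARG/LYS +1, ASP/GLU −1, HIS
0, overridable) receives sign(charge)·axis at unit magnitude. The
direction-only, unweighted convention was an open design choice; it
parallels the pocket normalization, and at LRT's qualitative level only
the direction pattern matters. Both the axis and the charge table are
arguments, so other conventions cost one line.

## The synthetic tetramer

`generateC4Tetramer()` produces the study conditions for every test:
four chains of 120 residues (480 nodes) with *exact* C4 symmetry. One
chain is built from six short α-helical columns (rise 1.5 Å/residue,
100°/residue, helix radius 2.3 Å) on a serpentine 3×2 grid, joined by
circular-arc loops sized so all consecutive-Cα distances stay in
[3.0, 4.5] Å. Gaussian jitter (σ = 0.05 Å, seeded) is applied *before*
symmetrization, then chains B–D are produced by exact 0/±1-entry
rotation matrices — so rotating the output by 90° about z and relabeling
chains reproduces the coordinates to machine precision. The subunit
radius (20 Å) was chosen once so adjacent subunits touch below the 10 Å
cutoff without interpenetrating; the generator verifies contact-graph
connectivity and tightens the radius by 10% (up to five attempts) if
needed. Six pocket residues (40, 42, 46, 58, 67, 108 by default)
surround a pseudo-ligand point: the pocket centroid displaced 2 Å toward
the symmetry axis, a geometric stand-in for a ligand's heavy-atom
center, which cannot exist at Cα resolution — only the force *direction*
derived from it is used.

What the toy emulates: exact fourfold symmetry, compact helical packing,
a connected 10 Å contact graph, an interior pocket, optional formal
charges. What it does not: realistic secondary-structure succession,
loop irregularity, a membrane environment, sequence-specific packing, or
the asymmetric coordinate noise of a real homology model. Passing tests
therefore demonstrate the *mechanics* of the pipeline exactly
(symmetry properties, oracles, contracts), not that any particular real
channel behaves a certain way. Two further caveats: the generator
guarantees graph connectivity, while full rigidity (exactly six null
modes) is enforced at diagonalization — some short-chain variants are
connected yet floppy and are rejected there; and real proteins are only
approximately symmetric, so the exact-symmetry results (e.g. identical
per-chain profiles to 1e-6) soften to approximate equalities on real
input.

## Mode classification and decomposition

For each non-null mode, the $N$ per-residue magnitudes are split into
four chain-quarters (node order is chain-major, so quarters are exactly
chains) and all six pairwise Pearson correlations are computed; the mode
is non-degenerate iff all exceed 0.95 strictly. A zero-variance quarter
forces its correlations to 0 (degenerate) with a message. Modes are
numbered by ascending eigenvalue, 1-based, *after* discarding the six
null modes; reports always use this global index, since numbering
schemes that include null or degenerate modes are not comparable across
conventions.

A known limitation of the quarter-correlation heuristic, visible on the
exactly symmetric toy: two-fold degenerate (E-representation) mode pairs
can have quarter correlations anywhere up to 1, and a minority of them
exceed 0.95, entering the non-degenerate set. Genuinely
symmetry-isolated modes are unambiguous — their quarter correlations are
1 up to machine precision — and eigenvalue pairing (relative gap
< 1e-6) can be used to recognize the two-fold pairs when needed; the
test suite asserts exactly these two reliable directions.

Overlaps use the absolute cosine $|v\cdot d|/(\lVert v\rVert\,\lVert
d\rVert)$ because eigenvector sign is arbitrary. Because the modes are
orthonormal, the best $k$-subset maximizing the combined overlap
$\sqrt{\sum a_i^2}$ is exactly the top-$k$ by individual $|a_i|$ —
greedy selection is provably optimal, and the cumulative overlap is
non-decreasing in $k$. Ties are broken toward the lower global index.

## The switch-off screen

Each noncovalent contact, together with its orbit under the chain
rotation A→B→C→D, forms one *class* (4 members; 2 for contacts between
opposite subunits, whose orbit is genuinely shorter). Classes partition
the noncovalent contacts — asserted on every run. Switching a class off
removes its springs in all subunits simultaneously, preserving symmetry.

Removing $m$ springs is the rank-$m$ downdate
$H' = H - UU^{\mathsf T}$, where the column for spring $(i,j)$ is
$\sqrt{\gamma}$ times the ±unit-separation pattern. Each such column is
orthogonal to all six rigid-body modes (trivially for translations; for
rotations because $d \times \hat d = 0$), so the pseudoinverse updates
by a range-restricted Woodbury identity:

$$C'f = Cf + CU\,(I - U^{\mathsf T}CU)^{-1}\,U^{\mathsf T}Cf,$$

and a singular capacitance matrix $I - U^{\mathsf T}CU$ (smallest
eigenvalue below 1e-8) signals that the removal created a mechanism —
such classes are flagged `disconnecting` and never scored. A full
Hessian-rebuild route is kept as the reference; both agree to ~1e-12 in
practice and to 1e-8 in the tests.

Because LRT units are arbitrary, "a change greater than 0.1" needs a
scale: both the baseline and the perturbed per-residue magnitude vectors
are divided by the *baseline's maximum* magnitude, so the threshold
means "10% of the peak baseline displacement". This is the package's
documented choice where the convention was open; it is scale-free and
reproducible. A class is significant iff the count of residues exceeding
the threshold reaches `minResidues` in every one of the four subunits.
Records are sorted by the minimum per-subunit count (descending), ties
broken by the representative pair's (chain, residue, residue) order for
determinism.

## Numerical choices, degenerate inputs

* Eigendecomposition is `eigen(symmetric = TRUE)` (LAPACK); eigenvalues
  are re-sorted ascending.
* Coincident nodes (zero contact distance) are an error in the Hessian;
  a ligand center coinciding with a pocket Cα is an error in the force
  (undefined direction).
* Zero-magnitude vectors are errors for overlaps (undefined cosine);
  a zero force yields a zero response, not an error.
* A baseline response that is identically zero skips normalization in
  the screen (nothing can be significant).
* First ALTLOC wins when reading PDB files; insertion codes are
  rejected; multi-model files use MODEL 1 with a warning. These dialect
  decisions are the package's own — Cα-only modeling needs one
  coordinate per residue, and reproducibility favours rejection over
  guessing.
* Provenance between network, spectrum, covariance and responses is
  tracked by a content fingerprint of the network (sizes and structural
  checksums) embedded in every derived object and report.

## Problem sizes

The shipped tests and the acceptance script run, by design, on sizes
where the mathematics can be checked exactly: oracle comparisons
(finite-difference Hessians, dense pseudoinverses, brute-force subset
search) on 5–50-node toys; symmetry, mode and screen behaviour on
200-node (50/chain) and 480-node (120/chain) tetramers; the full
switch-off screen covers all ≈1,400 classes of the default tetramer in
under a minute. On the default toy at default thresholds the screen
reports *no* significant contacts — the dense, homogeneous toy has no
load-bearing bottleneck, which is itself the expected behaviour; the
engineered keystone fixture in the test suite demonstrates the positive
case, ranking its single bridging class first.

## Known limitations

* Qualitative output only: no absolute displacement scale, no energies
  beyond the harmonic form, no kinetics.
* Two spring classes only; no distance-dependent or residue-specific
  stiffness, no special treatment of disulfides or salt bridges.
* The quarter-correlation rule can admit some two-fold degenerate modes
  (see above).
* Removing whole domains (as opposed to single contacts) is outside the
  LRT framework used here: that perturbs the Hamiltonian itself, not the
  force term.
* Single-class knockouts only; no simultaneous multi-class removals and
  no alanine-scan emulation (a mutation alters all interactions of a
  residue at once, which is a different experiment).
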