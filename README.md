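# PerturbANM

Coarse-grained mechanics of ligand- and voltage-modulated gating in
symmetric protein oligomers — an R implementation of the anisotropic
network model (ANM) / linear response theory (LRT) pipeline with
normal-mode decomposition and symmetric contact switch-off screening.

## The problem

Allosteric channels such as the tetrameric, cAMP-modulated HCN family
couple a cytosolic ligand-binding event to conformational change in a
distant transmembrane gate. When full atomistic simulation is out of
reach (e.g. only a Cα-level homology model exists), elastic network
models answer the qualitative questions: *which global motions does
ligand (un)binding excite, and which residue–residue contacts are
load-bearing for that response?*

`PerturbANM` is for structural bioinformaticians who want that analysis
as a reproducible pipeline: read (or synthesize) a Cα structure, build
the ANM, perturb it, decompose the response, and screen every contact —
with every stage testable against small exact oracles.

## The model

**ANM.** Each residue is a node at its Cα position; pairs closer than a
10 Å cutoff are springs. The potential is

V = ½ Σ_contacts γᵢⱼ (rᵢⱼ − rᵢⱼ⁰)²,

with γ = 82 RT/Å² for backbone-consecutive (covalent) pairs and
γ = 3.166 RT/Å² (the Miyazawa–Jernigan average) for all other contacts.
The 3N×3N Hessian **H** of V at equilibrium has exactly six zero
eigenvalues for a connected structure (rigid translations/rotations) —
enforced here as a hard contract.

**LRT.** The mechanical covariance is the Moore–Penrose pseudoinverse
**C** = Σ_{k>6} λₖ⁻¹ vₖ vₖᵀ, and the expected displacement under a
perturbing force **F** is Δ**r** = β **C F**. For ligand unbinding, **F**
puts a unit vector on each binding-pocket residue pointing from the
pseudo-ligand center to its Cα; for a transmembrane voltage it puts
sign(charge)·ẑ on each formally charged residue. Magnitudes are
arbitrary units — only ratios are meaningful.

**Mode decomposition.** Modes whose per-residue magnitude pattern
repeats in all four subunits (all six pairwise Pearson correlations
between chain-quarters > 0.95) are *non-degenerate*; the response is
expanded in the best k of them, with coefficients aᵢ = v̂ᵢ·Δr̂ and
overlap |v·d|/(‖v‖‖d‖).

**Switch-off screen.** Every noncovalent contact class (its orbit under
the C4 chain rotation, removed in all four subunits at once) is switched
off, the response recomputed — via an exact low-rank update of **C**,
cross-checked against full rebuilds — and classes whose removal changes
the normalized displacement by > 0.1 for at least 15 residues of *each*
subunit are flagged significant.

## Worked example

```r
library(PerturbANM)

s  <- generateC4Tetramer(seed = 1)      # exact-C4 toy tetramer, 120 res/chain
s
net <- buildContactMap(s)               # 10 A ANM contact network
net
sp  <- networkSpectrum(net)             # Hessian eigendecomposition
sp
f   <- bindingPocketForce(s, c(40, 42, 46, 58, 67, 108))
r   <- lrtResponse(pseudoInverse(sp), f)
r
cl  <- classifyDegeneracy(sp, s)
head(cumulativeOverlapReport(sp, cl, r@deltaR, kMax = 5))
```

prints

```
CaStructure: 480 residues, 4 chain(s) [A, B, C, D]
ElasticNetwork: 480 nodes, 6156 contacts (476 covalent, 5680 noncovalent), cutoff 10.0 A
NetworkSpectrum: 1440 modes, 6 null; softest non-null eigenvalue 0.01493 RT/A^2
LRTResponse: 480 residues, peak |dr| 0.08431 (arbitrary units)
  force: pocket[40,42,46,58,67,108] on chains ABCD (beta = 1)
  k         modes   overlap
1 1            15 0.7099671
2 2          15,9 0.7597775
3 3       15,9,35 0.8026662
4 4    15,9,35,66 0.8324868
5 5 15,9,35,66,34 0.8594920
```

The six null modes confirm one rigid connected body. A single soft
non-degenerate mode (global index 15) already overlaps the
pocket-opening response at 0.71, and the best three modes reach 0.80 —
the response is dominated by a handful of global, symmetry-preserving
motions rather than by localized ones. `screenContacts(net, f)` then
ranks every contact class by how strongly its removal reshapes this
response.

One-command orchestration with a report bundle (network TSV,
displacement profile, NMD field for external viewers, overlap table,
switch-off screen, JSON summary):

```r
runPipeline(defaultRunConfig(outputDir = "run1"))
```

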