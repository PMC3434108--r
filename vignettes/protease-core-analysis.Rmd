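---
title: "Methods: comparative analysis of serine-protease cores with triadcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of serine-protease cores with triadcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadcore)
```

## Overview

`triadcore` compares chymotrypsin-like (S1-family) serine protease
structures: rigid superposition with common-core detection, catalytic-triad
Cα geometry, alignment conservation under chymotrypsin numbering,
composition profiling, geometry-based model validation, and
secondary-structure / surface summaries. This vignette is the package's own
account of the methods: the procedures, the assumptions behind them, the
parameters a user may want to turn, and the places where a genuine design
choice had to be made.

## Structural input model

PDB text is parsed (via `bio3d`) into a flat atom table wrapped in the S4
class `StructureModel`. Policies applied at parse time:

* **First `MODEL` only.** The analysis targets X-ray structures and single
  predicted models; NMR ensembles are truncated to their first model.
* **Waters and non-amino-acid heteroatoms are dropped.** Neither enters any
  computation performed here.
* **Alternate locations.** One altloc is kept per atom: highest occupancy,
  ties resolved to the alphabetically first tag. Any deterministic rule
  works; this one matches common practice and keeps round trips stable.
* **Occupancy is clamped to [0, 1]** with a warning rather than an error —
  out-of-range occupancies are a data-entry artifact, not a reason to stop.
* Residue numbering follows the *author* numbering of the source file,
  because catalytic residues are conventionally named that way (His57,
  Asp102, Ser195 in chymotrypsin numbering; His328/Asp359/Ser438 and the
  like in specific models).

The PDB writer emits fixed-width records with 8.3f coordinates, so a
write–parse round trip is lossless at the format's own 10⁻³ Å precision;
a second round trip is exact.

## Superposition and the common core

`kabschFit()` solves the least-squares rigid superposition by SVD of the
3×3 covariance matrix with the standard sign correction, so the returned
rotation always has determinant +1: a mirror image is never "fit". Clouds
with fewer than three points or with rank < 2 (collinear) are rejected —
the rotation is not identifiable there.

How the "selected set of Cα atoms" defining a conserved core is chosen is
the one genuinely open question in this kind of analysis. The package's
procedure, `iterativeCoreSuperpose()`:

1. seed a residue correspondence from a Needleman–Wunsch global alignment
   of the two chain sequences (match +1, mismatch −1, gap −1 — sufficient
   for homologous chains; substitution matrices are deliberately not
   involved),
2. fit on the current Cα pairs,
3. drop *all* pairs whose post-fit Cα–Cα distance exceeds `pruneCutoff`,
4. repeat until the pair set is stable, oscillates, or `maxIters` (50) is
   reached.

Dropping all out-of-cutoff pairs per iteration (rather than one at a time)
keeps the procedure monotone: the pair set never grows, and the RMSD over
the retained set never increases, which guarantees termination. The cost is
that pairs are never re-admitted, so a chain whose divergent region
dominates the initial fit can end with a smaller core than a one-at-a-time
scheme would give. `pruneCutoff` defaults to 2.0 Å, the conventional
reporting threshold for predicted-model cores; tighter values (0.8–1 Å) are
appropriate when comparing experimental structures of close homologs.

`fractionMatched` is always reported relative to the **target** chain's
residue count. Published tables sometimes mix conventions (a self-reference
row at 100% alongside another 100% row with nonzero RMSD); fixing the
denominator to the target makes every row comparable.

## Catalytic-triad geometry and statistics

The triad is an explicit user input (chain + residue number per member),
optionally derived from `mapReferenceNumbering()`; automatic detection from
geometry alone is out of scope. A locator pointing at the wrong residue
type warns rather than errors, because predicted models can genuinely
differ. `aggregateTriadStats()` reports the mean and **sample SD (n − 1)**
per distance, always alongside `n`. Published survey tables of this kind
sometimes print per-column ±SDs far smaller than the dispersion of their
own listed values (plausibly standard errors or typos); the package
therefore reports only the SD it computes and labels the convention
(`sd_type = "sample"`).

Internal values are never rounded; display rounding is half-away-from-zero
and happens only at serialization (one decimal for Å distances and
percentages, three for RMSD) — the same arithmetic that reproduces
validation-table percentages exactly from their counts.

Stabilizing contacts use heavy-atom criteria, because hydrogens are absent
from most depositions: a hydrogen bond is donor–acceptor ≤ 3.5 Å with
antecedent–donor–acceptor angle ≥ 120°, both configurable; a disulfide is
Cys Sγ–Sγ ≤ 2.3 Å, a conventional bound comfortably covering observed
bridges (≈2.04 Å). Pairs within two covalent bonds (inferred from
distances and covalent radii) are excluded.

## Conservation, numbering, composition

Column occupancy = rows carrying the modal non-gap residue / **all** rows.
Keeping gapped rows in the denominator is the convention under which
published occupancy percentages of the form 76% / 71% over 21 aligned
sequences correspond to integer counts (16/21, 15/21); `n` is always
reported next to the percentage so the denominator is never ambiguous.
Symbols follow the classic progressive-aligner groups (bundled via
`conservationGroups()`, overridable): `*` only for full-occupancy identical
columns; `:` / `.` when all non-gap residues fall in one strong / weak
group — gaps disqualify `*` but not the group symbols.

Composition classes follow the EMBOSS convention (`compositionClasses()`).
The published class lists overlap ambiguously for *polar*; the package
defines `polar` as the complement of `nonpolar` over the 20 standard
residues, which preserves the invariant nonpolar + polar = 100% used in the
tests. Outlier flagging across a structure set is strict: a value must
exceed mean ± 1 sample SD strictly, so identical profiles (SD 0) are never
flagged.

## Model-quality metrics

Dihedrals use the IUPAC definitions; a peptide C–N distance above 2.5 Å is
a chain break and the affected dihedrals are undefined rather than wrong.
The four-region Ramachandran map is a bundled 10°×10° grid: rectangular
cores approximating the β, right-handed-α and left-handed-α basins of the
classic PROCHECK map, with the additional-allowed and generously-allowed
regions as one and two 8-neighbour dilations of the cores (wrapping at
±180°). This is an approximation: published region polygons are not
reproduced exactly, and the map is replaceable via the `map` argument.
Percentage reproduction of published tables goes through the *counts*
(`ramaPercentages()`), so the map's boundaries are not load-bearing for
that. Glycine and proline are classified with the same map, matching
single-total summary tables; the denominator (residues with both φ and ψ)
is reported explicitly.

The clashscore counts heavy-atom van der Waals overlaps > 0.4 Å per 1000
heavy atoms, excluding pairs within three inferred covalent bonds. Because
no hydrogens are added, absolute values are *not* comparable with
added-hydrogen tools; the score is for comparing structures processed the
same way. Bond-geometry RMSD compares backbone (and Cα–Cβ) bonds and
angles against the Engh–Huber values in `standardGeometry()`; unrecognized
or break-spanning terms are skipped and counted.

## Surface measures

Shrake–Rupley SASA uses a golden-spiral point set (default 960 points,
1.4 Å probe). Each atom's point sphere is oriented in a molecule-fixed
local frame built from its two nearest non-collinear neighbours, so the
computed area is exactly invariant under rigid motion of the model instead
of drifting with the lab-frame orientation of the point grid; convergence
in point count is property-tested (960 vs 4000 within 2%).

The electrostatic surface classifier is deliberately qualitative: published
surface figures come from visualization tools whose potential model and
colour thresholds are unstated, so no quantitative reproduction is
attempted. Formal charges sit at side-chain charged-group centroids
(Asp/Glu −1, Lys/Arg +1, His configurable and neutral by default), the
reduced Coulomb sum V(p) = Σ qᵢ/d carries no dielectric — the dielectric is
absorbed into the neutral band ±t (default 0.05 charge/Å) — and the output
is the negative/neutral/positive partition of surface points. Its
guarantees are structural: antisymmetry under mirrored charges and
monotonicity of the neutral fraction in t.

Secondary structure is assigned from dihedral windows (helix φ ∈ [−100,
−30], ψ ∈ [−80, −5]; strand φ ∈ [−180, −40], ψ ∈ [60, 180] ∪ [−180,
−170]; minimum run lengths 4/3) rather than hydrogen-bond patterns. A
DSSP-style assignment is better on real structures; the window rule was
chosen because it is exactly verifiable on synthetic dihedral fixtures and
its parameters are all visible. Element counts from ribbon figures are not
reproduction targets.

## Synthetic fixtures: what they are and are not

The generators exist so every code path is testable without downloads, with
known ground truth:

* `makeIdealSSE()` builds N/CA/C/O backbones by internal-coordinate (NeRF)
  construction at constant (φ, ψ) — (−57, −47) helix, (−120, 120) strand —
  using exactly the bond lengths/angles of `standardGeometry()`. Hence
  `backboneDihedrals()` recovers the constructed dihedrals to < 10⁻³ ° and
  `bondGeometryRMSD()` is zero by construction; the ideal helix also
  exhibits the O(i)···N(i+4) hydrogen-bond ladder at the expected geometry.
* `makeToyProtease()` places a His/Asp/Ser Cα triangle *exactly* at the
  target distances — defaulting to (6.4, 8.4, 9.8) Å, the consensus
  experimental means for the S1 triad — between two strand lobes, then
  adds i.i.d. Gaussian coordinate noise. Default lobe size is 12 residues:
  large enough to exercise superposition, alignment seeding and quality
  metrics, small enough that the full suite runs in seconds.
* `applyRandomTransform()` draws a uniform quaternion rotation and a
  translation in [−50, 50]³ and returns the applied transform for recovery
  tests.
* `makeSyntheticAlignment()` gives exact control of per-column occupancy
  (the conserved residue appears in exactly ⌈occupancy × rows⌉ rows;
  remaining rows draw from the other 19 residues), with 10% background
  gaps.

Every generator takes a `seed` and restores the caller's RNG state: no
global random state leaks, and identical seeds give bitwise-identical
output.

These fixtures are geometric stand-ins, **not folded proteins**: no
packing, no side chains beyond what a test constructs, no real β-barrel
topology. Tests passing on them demonstrate that the *computations* are
correct (distances, fits, pruning, counting, classification arithmetic) —
not that the biological conclusions drawn from real structures would be
reproduced, which additionally depends on inputs this package deliberately
treats as external (the structures themselves, the alignment, the triad
locators).

## Numerical conventions and problem sizes

* Rotations are validated orthonormal within 10⁻⁸ with det = +1.
* Alignment traceback ties prefer diagonal > up > left, making alignments
  deterministic; optimality is tested against exhaustive enumeration for
  short sequences.
* Statistical recovery tests use 100 seeded replicates at σ = 0.1 Å and a
  3-SEM band; the Kabsch oracle uses 100 random 5-point cloud pairs against
  a 30°-grid brute-force search with Nelder–Mead refinement. These sizes
  were chosen so the whole suite completes in well under a minute while the
  Monte-Carlo bands stay tight.
* Degenerate inputs fail loudly and specifically: no ATOM records,
  malformed coordinate fields (named by line), ragged alignment rows (named
  by id), collinear point clouds, cores shrinking below three pairs (with
  the last good iteration in the message), triads that are not three
  distinct residues.

## The pipeline interface

`runPipeline()` consumes a validated configuration (R list or YAML file:
structure entries with paths, chains, taxon labels and triad locators; a
reference entry; optional alignment and reference sequence id; cutoffs;
seed) and produces a `StudyReport`; `writeReport()` serializes it as TSV
(survey-table layout, display rounding applied only here) and
full-precision JSON that is byte-identical across reruns of the same
configuration. The package's command-line story is intentionally thin:
these functions plus small user scripts *are* the interface — shipping a
separate CLI binary would duplicate the R API without adding capability.

## Known limitations

* The clashscore is heavy-atom only; absolute values differ from
  added-hydrogen tools.
* The Ramachandran map approximates the classic region shapes; per-residue
  region labels near boundaries should not be over-interpreted.
* The dihedral-window SSE assignment under-calls elements with distorted
  backbone dihedrals that hydrogen-bond-based methods would still accept.
* The surface classifier is qualitative by design; it is not a substitute
  for Poisson–Boltzmann electrostatics.
* Rotamer analysis and database-fitted quality scores are out of scope.
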