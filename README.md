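# triadcore

Comparative structural analysis of chymotrypsin-like (PA-clan, S1-family)
serine protease cores in R.

## The problem

S1-family serine proteases — trypsin, chymotrypsin, elastase and their
bacterial, fungal, plant, protozoan and archaeal homologs — share a fold of
two β-barrels whose interface carries the catalytic triad His57–Asp102–Ser195
(chymotrypsin numbering). When homologous structures (experimental or
predicted) are compared across taxa, the questions are always the same:

* How much of the chain superposes rigidly, and at what RMSD — i.e. what is
  the structurally conserved common core?
* Are the catalytic-triad Cα–Cα distances (Asp–His, His–Ser, Asp–Ser)
  conserved, and with what spread across structures?
* Which alignment positions around the triad are conserved, at what
  occupancy, under a common chymotrypsin reference numbering?
* Do predicted models have sound stereochemistry — Ramachandran φ/ψ
  distribution, steric clashes, bond lengths/angles against standard values?
* How do secondary-structure content, amino-acid composition and surface
  electrostatic character differ between homologs?

`triadcore` implements that whole workflow as composable, deterministic
functions, plus seeded synthetic-structure generators so every stage is
testable offline.

## What is computed

* **Superposition** — Kabsch least-squares fitting: the proper rotation *R*
  and translation *t* minimising
  RMSD = √(1/N Σᵢ ‖R xᵢ + t − yᵢ‖²), solved by SVD of the covariance matrix
  with the usual sign correction (no reflections). The *common core* is
  found by seeding a residue correspondence from a Needleman–Wunsch global
  alignment, then iterating fit → drop pairs with post-fit Cα–Cα distance
  above a cutoff (default 2 Å) → refit, until stable. Reported: final RMSD
  and the matched fraction of target residues.
* **Triad geometry** — the three Cα–Cα distances of a located His/Asp/Ser
  triad; across structures, their mean ± sample SD (n − 1), printed at one
  decimal, half away from zero.
* **Conservation** — per-column occupancy (rows carrying the modal non-gap
  residue over *all* rows) with `*` / `:` / `.` symbols from the classic
  strong/weak residue groups, and chymotrypsin reference numbering mapped
  through the alignment.
* **Model validation** — IUPAC φ/ψ/ω dihedrals; a four-region Ramachandran
  summary (counts and percentages); a heavy-atom clashscore (van der Waals
  overlaps > 0.4 Å per 1000 atoms, covalent neighbours within three bonds
  excluded); bond length/angle RMSD against Engh–Huber standard values.
* **Composition** — molar percentages over EMBOSS-style physico-chemical
  classes (tiny, small, aliphatic, aromatic, nonpolar, polar, charged,
  basic, acidic; `polar` is the 20-residue complement of `nonpolar`, so the
  two sum to 100%), with > 1 SD outlier flagging across a structure set.
* **Surface** — Shrake–Rupley solvent-accessible surface area (1.4 Å probe)
  and a qualitative reduced-Coulomb classifier V(p) = Σ qᵢ/d(p, i) over
  charged-group centroids, thresholded into negative/neutral/positive.

## Worked example

Three synthetic protease-like structures are built with the triad placed at
the S1-family consensus distances (6.4, 8.4, 9.8 Å) plus 0.1 Å coordinate
noise, written to PDB, and run through the pipeline:

```r
library(triadcore)
td <- tempdir()
entries <- lapply(1:3, function(i) {
  tp <- makeToyProtease(noiseSigma = 0.1, seed = i, modelId = sprintf("toy%d", i))
  path <- file.path(td, sprintf("toy%d.pdb", i))
  writeStructure(tp$model, path)
  list(path = path, model_id = sprintf("toy%d", i), chain = "A",
       taxon = "synthetic", triad = list(his = "A:101", asp = "A:102", ser = "A:103"))
})
report <- runPipeline(list(reference = "toy1", seed = 1, structures = entries))
report
#> StudyReport: 3 structures (reference 'toy1')
#>   model_id     taxon fraction_matched  rmsd d_asp_his d_his_ser d_asp_ser
#> 1     toy1 synthetic            100.0 0.000       6.3       8.2       9.7
#> 2     toy2 synthetic            100.0 0.234       6.5       8.3       9.8
#> 3     toy3 synthetic            100.0 0.231       6.4       8.5       9.8
#> TriadStats over n = 3 structures (sample SD):
#>   d_asp_his  6.4 +/- 0.10 A
#>   d_his_ser  8.3 +/- 0.14 A
#>   d_asp_ser  9.8 +/- 0.03 A
```

Each row is one structure: the matched core fraction and RMSD against the
reference, then the three triad distances; the footer is the cross-structure
mean ± sample SD. The noise-free construction targets are recovered to
within the PDB field precision and the added noise.

A compiled survey of published triad distances for 16 experimentally
determined S1 proteases ships as example data:

```r
sv <- read.delim(system.file("extdata", "s1_triad_survey.tsv", package = "triadcore"))
st <- aggregateTriadStats(sv[sv$source == "experimental",
                             c("d_asp_his", "d_his_ser", "d_asp_ser")])
formatTriadStats(st)
#>    d_asp_his    d_his_ser    d_asp_ser
#> "6.4 ± 0.22" "8.4 ± 0.47" "9.9 ± 0.32"
```

The triad separation is tightly conserved across two billion years of
divergence — the Asp–His mean sits at 6.4 Å with a sample SD of ~0.2 Å.
Ramachandran percentages recompute from validation-table counts:

```r
ramaPercentages(c(89, 21, 4, 3))
#> [1] 76.1 17.9  3.4  2.6
```

## Scope notes

Homology/threading model *building*, energy minimisation, rotamer analysis
and database-fitted quality scores (Verify3D/ProSA/ERRAT) are out of scope:
this package analyses structures it is given. The synthetic generators
produce geometric stand-ins, not folded proteins — see the methods vignette
(`vignettes/protease-core-analysis.Rmd`) for what they do and do not
exercise.
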