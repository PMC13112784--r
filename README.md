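# nciprofiler

Residue-centric non-covalent interaction profiling for protein
complexes, built for antibody mutation analysis.

When a designed mutation replaces one or two antibody residues, whether
the new side chains "work" is decided by the contacts they make with
the rest of the antibody, the antigen, and ordered water — and much of
that signal sits in interactions that standard energy terms and most
interaction profilers ignore: CH···O and CH···π weak hydrogen bonds,
sulfur contacts (S···O, SH···π, …), and orthogonal C=O···C=O
dipole–dipole arrangements.  `nciprofiler` detects, labels, and counts
**36 operationally defined interaction types** around designated
residues, including bridges through single water molecules, and turns
them into fixed-length descriptor vectors suitable for statistics and
machine learning.

The package is aimed at structural bioinformaticians and antibody
engineers who have protonated complex structures (PDB or TRIPOS MOL2)
and want reproducible, rule-based interaction inventories rather than
manual inspection in a molecular viewer.

## What it computes

* **Typed structures** — SYBYL atom/bond types and template partial
  charges assigned from a built-in residue dictionary (pdb2pqr or
  GROMACS hydrogen-naming dialects), or read directly from MOL2.
* **Interaction hits** — every rule evaluated between the target (M)
  residues and their environment, one highest-priority label per atom
  pair.  The three core geometric definitions, implemented exactly:
  * CH···O: d(H:A) ≤ 3.22 Å, ∠(D:H:A) ≥ 94.58°, vdW-radii sum + 1 Å
    gate, plus donor/acceptor neighbour conditions;
  * CH···π: perpendicular foot of H within 1.4 × the ring radius of
    the centroid, d(A:H) ≤ 3.195 Å (or ≤ 3.325 Å with
    ∠(D:H:A) ≥ 124.455°);
  * orthogonal multipolar: |δ⁺−δ⁻| ≥ 0.2 in both dipoles, Dp1⁻···Dp2⁺
    within vdW sum + 0.7 Å, approach angles in [75°,105°], ≤ 35°, and
    ≥ 150°.
  Hydrogen bonds and electrostatics split at a heavy-atom distance of
  3.2 Å; vdW contacts are the residual unlabeled pairs.
* **Descriptors** — grouped (30 counts: 28 partner-erased labels +
  `M##S` + `M##S##`) or individual (water interactions resolved by
  label: 11 + 11 + 55 water keys), optionally extended by a
  backbone-dependent **rotamer energy** `E = −RT ln(p/p_max)`.
* **Structure labeling** — symmetry-aware side-chain RMSD (ring flips,
  carboxylate and guanidinium swaps) against a reference conformation,
  with the < 1 Å crystal-likeness rule.
* **Evaluation harness** — group-shuffle partitioned xgboost training
  with MCC early stopping and permutation importance.
* **Outputs** — deterministic TSV hit tables and PyMOL scripts
  (hydrogen bonds blue, electrostatics cyan, X–H···π orange, CH···O
  pink, orthogonal multipolar yellow; vdW omitted).

## Worked example

The package ships a fully typed toy antibody–antigen–water complex
with an engineered, hand-verified interaction inventory:

```r
library(nciprofiler)

toy <- make_toy_complex()          # target H:57, class M
det <- detect_interactions(toy$system)
length(det$hits)                   # 12
length(det$bridges)                # 1

g <- aggregate_descriptors(det$hits, det$bridges, mode = "grouped")
g[g > 0]
#>  M#HB_NH_O# M#Ele_NH_O#    M#CH_PI#     M#CH_O#      M#vdW#        M##S      M##S##
#>           1           1           1           1           6           2           1

descriptor_name(det$bridges[[1]])
#> "M#HB_NH_O#S#HB_OH_O#Ag"
```

Reading the counts: the lysine-like target donates one hydrogen bond to
an antigen carbonyl (`M#HB_NH_O#`), makes one long-range electrostatic
contact (3.5 Å, `M#Ele_NH_O#`), one CH···O and one CH···π contact with
antibody neighbours, six residual vdW contacts, touches two waters
(`M##S`), and reaches the second antigen residue through one
water-mediated hydrogen-bond bridge (`M##S##`).

The rotamer-energy term penalises rare side-chain conformations:

```r
rotamer_energy(p = 0.3, p_max = 0.6)   # 0.4132 kcal/mol  (-RT ln 1/2 at 300 K)
```

Single-rule probe systems are available for every label, e.g.
`make_probe("OMulPol")`, and a command-line front-end lives in
`inst/scripts/nciprofile.R` (`detect`, `descriptors`, `rotamer-energy`,
`rmsd`, `fixtures` subcommands).

## Package layout

| Path | Contents |
| --- | --- |
| `R/structure_io.R`, `R/typing_dictionary.R` | PDB/MOL2 I/O, SYBYL typing, partner classes |
| `R/geometry.R`, `R/rings.R` | vector kernel, ring perception |
| `R/rules.R`, `R/rule_eval.R` | the 36-label registry and predicate evaluators |
| `R/engine.R` | detection, priority resolution, water bridges, TSV/PyMOL output |
| `R/descriptors.R` | descriptor naming and aggregation |
| `R/rotamer.R`, `R/rmsd.R` | rotamer energies, symmetry-aware RMSD |
| `R/ml.R` | group-aware xgboost harness |
| `R/fixtures.R` | synthetic probes, toy complex, synthetic learning task |
| `inst/extdata/` | example configs and a synthetic rotamer-library fragment |
| `vignettes/interaction-profiling.Rmd` | methods, parameter defaults, design rationale |
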