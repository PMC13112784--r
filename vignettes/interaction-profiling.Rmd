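---
title: "Residue-centric interaction profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-centric interaction profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nciprofiler)
```

## The problem

When an antibody residue is mutated, the change in binding behaviour is
largely decided by the non-covalent contacts the new side chain makes
with its surroundings: the rest of the antibody, the antigen, and
ordered water.  Conventional energy terms (electrostatics plus van der
Waals) miss much of this picture — weak hydrogen bonds such as CH···O
and CH···π, sulfur contacts, and orthogonal dipole–dipole arrangements
are all real, directional, and individually small.  `nciprofiler`
detects and labels 36 operationally defined interaction types around
designated residues of a protein complex, converts them into fixed-
length descriptor vectors, and provides the supporting machinery a
mutation-analysis workflow needs: SYBYL atom typing, a rotamer-energy
term, symmetry-aware side-chain RMSD labelling, and a group-aware
gradient-boosting evaluation harness.

## Input model

Structures enter either as protonated PDB files, which are typed
through a built-in residue dictionary, or as TRIPOS MOL2 files that
already carry SYBYL atom types, bond types, and per-atom partial
charges (the charge column is mandatory — two rules gate on charges).
Residue identity is `(chain, resseq, icode)` throughout; nothing is
renumbered.  Alternate-location records other than blank or `'A'` are
dropped, and a residue represented only by such records is an error.

The typing dictionary covers the 20 canonical amino acids, the
disulfide cysteine variant, and water, in two hydrogen-naming dialects
(pdb2pqr and GROMACS ff99SB-ildn).  Its partial charges are a
Gasteiger-like template set written for this package.  They are
internally consistent rather than tied to any particular published
derivation: the only charge-sensitive predicate in the rule set is the
dipole gap gate (|δ⁺ − δ⁻| ≥ 0.2), which carbonyl, carboxylate, and
amide groups clear by a wide margin under any reasonable scheme, and
which aliphatic C–C and C–H pairs fail equally robustly.

Each residue is assigned a partner class: `M` (the mutated/designated
residues — one for a single-point analysis, two for a double-point
pair), `Ab` (antibody), `Ag` (antigen), or `S` (water).  Classes drive
descriptor naming only; the geometry rules are class-blind.

## Interaction rules

The registry holds 28 direct labels plus 5 metal and 3 ion labels.
Three rule families have fully printed geometric definitions, which are
implemented verbatim:

* **CH···O** (and by template every X–H···Y weak hydrogen bond):
  heavy-atom distance within the vdW-radii sum plus a 1 Å buffer; the
  donor closer to the acceptor than the donor's covalent neighbours
  are; the donor closer to the acceptor than the acceptor is to its own
  neighbours; d(H:A) ≤ d(D:A); d(H:A) ≤ 3.22 Å; ∠(D:H:A) ≥ 94.58°.
  Conditions involving neighbours that do not exist are vacuously true.
* **CH···π** (and every X–H···π): per ring atom A, the vdW gate and
  donor-neighbour condition, d(H:A) ≤ d(D:A), the perpendicular foot
  `Nr` of the donor hydrogen on the ring plane within 1.4 × d(cn:A) of
  the centroid `cn`, and either d(A:H) ≤ 3.195 Å or
  3.195 < d(A:H) ≤ 3.325 Å with ∠(D:H:A) ≥ 124.455°.  One hit per
  (donor, ring) pair, booked at the nearest qualifying ring atom.
* **Orthogonal multipolar**: both bond dipoles with charge gap ≥ 0.2;
  d(Dp1⁻:Dp2⁺) within the vdW sum + 0.7 Å and not exceeding
  d(Dp1⁺:Dp2⁺); ∠(Dp2⁻:Dp2⁺:Dp1⁻) in [75°, 105°];
  ∠(Nr:Dp1⁻:Dp2⁺) ≤ 35° and ∠(Nr:Dp1⁻:Dp1⁺) ≥ 150°, with `Nr` the foot
  of Dp1⁻ on the sp² plane of dipole 2's group.

Canonical polar contacts are evaluated with the same X–H···Y template
(angle threshold 90°, no H···A cap) and then split on the heavy-atom
distance: ≤ 3.2 Å is a hydrogen bond (`HB_*`), beyond 3.2 Å but inside
the vdW gate is electrostatic (`Ele_*`).  The boundary value itself
classifies as a hydrogen bond.  Salt bridges are deliberately not a
separate category — they fall into whichever of the two distance
classes applies.

The remaining rules are reconstructions, declared as such, and every
threshold is externalised to the criteria config so alternative values
can be dropped in without code changes:

* X–H···Y rules beyond CH···O default to the CH···O caps
  (3.22 Å / 94.58°) unless overridden per rule.
* Chalcogen contacts (S···O, S···N, S···S) use the heavy-atom vdW gate
  with two restrictions: the donor sulfur must be a σ-hole donor
  (divalent, two heavy substituents, no bonded hydrogen — thioether or
  disulfide sulfur), and the acceptor must be sp² or charged (sp³
  water oxygen is ineligible).  The donor restriction is standard
  chalcogen-bond chemistry and also keeps S-H···Y contacts assignable:
  without it every SH···O pair would be shadowed by the
  higher-priority S···O label at the same atom pair.
* Face-to-face π stacking (`PI_PI`) uses centroid distance ≤ 5.5 Å and
  interplanar angle ≤ 35°; edge-to-face geometries are CH···π by
  construction.
* `Dipo` (bond-dipole) is reconstructed as an antiparallel
  dipole–dipole contact: both gaps ≥ 0.2, opposing poles within the
  vdW gate, dipole vectors within [135°, 180°] of antiparallel.
* Metals (Fe, Zn, Ca, Mg, Ni) and ions (Na, K, Cl) coordinate N/O/S
  atoms within 3.0 Å and 3.5 Å respectively.

Van der Waals contacts are the residual category: any heavy-atom pair
within the vdW-radii sum plus buffer that carries no other label.  The
vdW radii default to the Bondi set and can be replaced from a radius
file.

### Priority resolution

Several rules can accept the same atom pair; only the highest-priority
label is kept.  The default order is metals/ions > hydrogen bonds >
electrostatics > orthogonal multipolar > bond dipole > chalcogen >
X–H···π > π stacking/S···π > weak X–H···Y hydrogen bonds > vdW, fully
overridable from a priority file.  Resolution is per unordered atom
pair, using one representative heavy-atom pair per hit (donor/acceptor;
donor/nearest ring atom for π rules; Dp1⁻/Dp2⁺ for dipole rules).

### Water bridges

Waters are ordinary environment residues for direct detection (an
M–water hit contributes to `M##S`).  A bridge requires one M–water leg
and one water–partner leg through the *same single* water; water chains
are not followed.  All leg pairings are enumerated; grouped aggregation
then counts each bridge once into `M##S##`.

## Descriptors

Direct hits are named `M#<label>#<class>`, bridges
`M#<label1>#S#<label2>#<class>`.  Grouped aggregation erases the
partner class (28 direct keys), pools direct water contacts (`M##S`)
and bridges (`M##S##`) — 30 keys, 31 with the rotamer-energy term.
Individual aggregation keeps water interactions resolved by label: 11
single-leg `M#X#S` keys (the labels whose participant constraints a
water molecule can satisfy — derived by satisfiability against a water
template, not hard-coded), 11 same-label bridge keys, and
C(11,2) = 55 unordered mixed-label bridge keys.  Metal and ion labels
are excluded from descriptor vectors by default.

## Rotamer energy

The descriptor vectors measure favourable contacts; they say nothing
about how strained the side-chain conformation itself is.  The
rotamer-energy term fills that gap:

$$E = -RT \ln(p / p_{\max}),\qquad R = 0.001987\ \mathrm{kcal/(mol\,K)},\ T = 300\ \mathrm{K},$$

where `p` is the backbone-dependent probability of the observed rotamer
and `p_max` the largest probability at the same backbone bin.  The
energy is non-negative and zero exactly at the modal rotamer.  For a
residue pair the probabilities are multiplied (independence
assumption), which makes the pair energy exactly the sum of the two
single-residue energies; context-dependent rotamer coupling is out of
scope.  Backbone angles are snapped to the nearest populated library
bin (exact half-bin ties round away from zero) and observed χ angles to
the rotamer with the smallest wrapped χ distance — both choices favour
determinism over interpolation, which is off by default.  A zero
probability is clamped to 1e-6 with a warning rather than returning an
infinite energy.

## Crystal-likeness labelling

A modeled side chain is compared with its reference over side-chain
heavy atoms excluding Cβ, matched by atom name, with the RMSD minimised
over the residue's chemically indistinguishable permutations (Phe/Tyr
ring flips, Asp/Glu carboxylate swaps, Arg guanidinium swaps).  No
superposition is performed: the model shares the reference backbone, so
the shared frame is the comparison frame.  RMSD < 1 Å (configurable to
0.8 or 1.2 Å for robustness sweeps) labels the conformation
crystal-like; a pair is crystal-like iff both residues are, with a
pooled-atom joint RMSD available as an alternative.

## Learning harness

The harness trains an xgboost binary classifier on descriptor tables
under group-shuffle partitioning: structure clusters (in real data, CDR
sequence clusters) never straddle partitions, so evaluation measures
generalisation to unseen antibody families rather than memorisation.
Defaults follow the dataset-scale protocol: cluster shares 64/16/20 for
building / early stopping / evaluation, learning rate 0.025, a
20,000-round cap, and early stopping after 100 rounds without
improvement in the Matthews correlation coefficient on the held-out
partition.  MCC uses the zero-denominator → 0 convention.  Permutation
importance (default 100 shuffles per feature) reports the mean drop
from the baseline MCC; a small config-driven grid search is provided
but the shipped defaults are deliberately modest.

## Numerical choices

* **Ring planes** are principal-axis best fits, robust to slight
  non-planarity.  The planarity gate (0.35 Å) charges each member its
  leave-one-out deviation — the distance from the plane fitted to the
  *other* members — so a single puckered atom is measured at its full
  displacement instead of a tilt-absorbed residual.
* **`Nr` in X–H···π rules** projects the donor *hydrogen* (configurable
  in principle to the heavy donor); in the orthogonal multipolar rule
  the reference plane is the sp² plane of the *acceptor* dipole's
  group, which reproduces the canonical perpendicular C=O···C=O motif.
  An exactly in-plane Dp1⁻ is rejected (the approach cannot be
  perpendicular).
* **Analyzed atoms** of an M residue are its side-chain heavy atoms and
  their hydrogens; backbone atoms are optional via a flag.  Environment
  partners always include backbone atoms.
* **Culling** considers environment residues with any atom within 8 Å
  of the analyzed atoms.  The widest default gate is ≈ 4.6 Å
  (S + S + buffer) and π-rule reach stays below 7 Å, so culling is
  lossless; the test suite asserts equality with an unculled run.
* **Determinism**: hits are sorted by (target, partner, label, atom
  serials); repeated runs on identical input produce byte-identical
  output files.  All stochastic components (jitter, splits, training,
  permutation importance) take explicit seeds.

## What the synthetic fixtures do and do not show

Every rule ships with a satisfying and a violating probe system —
minimal two-residue geometries with idealized bond lengths (C–H 1.09 Å,
O–H 0.96 Å, S–H 1.34 Å, C=O 1.23 Å), template charges, and margins of
at least 0.05 Å / 2° to every threshold, so accept/reject decisions are
never boundary cases.  A toy antibody–antigen–water complex (one
lysine-like target, four protein neighbours, a bridging and a
non-bridging water, ~30 atoms) exercises detection, priorities, water
bridging, and aggregation end to end against a hand-derived expected
descriptor vector and an independent all-pairs oracle.

The fixtures validate the *rules*, not chemistry: they contain no
conformational strain, no crowded interfaces with hundreds of competing
candidates, no protonation ambiguity, and no coordinate noise beyond
optional Gaussian jitter.  Passing them shows the geometric predicates,
priority resolution and bookkeeping are correct; it does not certify
hydrogen placement or charge quality on real structures, which remain
the responsibility of the upstream protonation step.  The synthetic
learning task (400 rows, 30 count features, 20 clusters, two Gaussian
profiles separated by 4 sd on 3 features) is likewise separable by
construction: it verifies the harness, not the biology.

These problem sizes — ≤ 40-atom probes, a ~30-atom complex, a
400-row training table — were chosen as the smallest systems that
exercise every code path; the full suite runs in well under a minute.

## Known limitations

* Thresholds for the rules beyond the three printed families are
  reconstructions; users with authoritative values should supply them
  through the criteria config.
* Halogen bonds are intentionally absent from the registry.
* No energetic scoring of interactions is attempted; counts are the
  output.
* Hydrogen-bond-network optimisation, protonation-state prediction and
  tautomer choice are upstream preconditions, not package features.
* The rotamer independence assumption ignores sequence- and
  context-dependent rotamer coupling.
* The harness evaluates descriptor informativeness; it is not a binding
  affinity predictor.

## A worked example

```{r example}
toy <- make_toy_complex()
det <- detect_interactions(toy$system)
length(det$hits)
length(det$bridges)
g <- aggregate_descriptors(det$hits, det$bridges, "grouped")
g[g > 0]
descriptor_name(det$bridges[[1]])
```
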