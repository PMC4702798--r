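---
title: "Methods: pocket numbering, fingerprints and conformation classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pocket numbering, fingerprints and conformation classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinpocket)
```

kinpocket annotates kinase catalytic-domain structures on a single shared
coordinate system — the 85-residue binding-site frame — and derives from it
the interaction fingerprint, conformation classes, subpocket flags, water
assignments and a quality score. This vignette documents the models and the
numerical choices behind each stage, which parameters matter, and what the
bundled synthetic fixtures do and do not demonstrate.

## The master frame and pocket numbering

The unit of comparison is a pocket slot: 85 positions spanning the N-lobe
strands, the Gly-rich loop, the αC helix, the gatekeeper and hinge, the
catalytic loop and the xDFG motif (`kp_regions()` lists the region table;
labels render as `aa.region.index`, e.g. `D.xDFG.81`). The bundled master
profile is the 85-position consensus itself: in this package's synthetic
world the catalytic domain *is* the pocket, which keeps the alignment
problem well-posed without shipping a full kinome alignment. Real kinase
domains are ~250 residues with the pocket positions interleaved; mapping
such a sequence requires a master profile with the same column convention,
which can be dropped in as a FASTA + region-table pair.

Sequences are aligned to the profile with a global–local
Needleman–Wunsch/Smith–Waterman hybrid (global in the master, local in the
query), BLOSUM62, gap open 11, gap extend 1. These are the classic
protein-search parameters; determinism matters more here than sensitivity,
and ties resolve to leftmost gap placement by the alignment engine. An
alignment score below 60 (configurable) is rejected as "not a kinase
domain": the self-alignment of the 85-residue consensus scores ≈ 430, and
unrelated sequences of that length score near or below zero, so the floor
is permissive to divergent kinases while rejecting noise.

The master structural frame is a hand-built 3D template of the 85 slots:
backbone N/Cα/C/O everywhere, Cβ on non-glycines, and full side chains for
the functionally loaded residues (K17, E24, T45, Y47, D70, D81, F82). It is
geometric, not physical — no energies, no realistic rotamers — but it fixes
the axis convention every descriptor depends on: y is the DFG-flip axis,
the hinge sits at +x, the αC helix at −x, the Gly-rich loop at +z.

## Superposition and the quality score

Structures are superposed onto the master frame by least-squares rigid
fitting (Kabsch, via SVD with determinant correction) of the backbone atoms
of the anchor slots: hinge 46–48, catalytic loop 68–75, xDFG 80–82. These
regions are the most conformation-stable parts of the fold, which is why
they anchor the fit; side chains are excluded because they move with the
activation state. Anchors that are GAP are dropped; fewer than three mapped
anchor residues is an error. Two RMSDs are reported: over the anchor
backbone (the fit residual) and over the backbone of all mapped slots (how
far the whole pocket sits from the canonical frame).

The quality score compresses processing quality into 0 (bad) … 10
(flawless):

```
score = clamp(10 − w1·max(0, rmsd_anchor − 0.8) − w2·max(0, rmsd_pocket − 2.2)
               − w3·n_missing_residues − w4·n_missing_atoms, 0, 10)
```

with default weights (4, 1, 0.4, 0.1). The RMSD allowances 0.8 Å and 2.2 Å
are the levels at which a well-processed kinase structure typically sits,
so only the excess is penalised; the weights encode that a bad anchor fit
is worse than a loose pocket, and a missing residue worse than a missing
atom. The functional form is a package design choice — the requirement it
implements is the 0–10 range, the ingredient list, and monotone
non-increase in every penalty; all weights live in the function signature.

## Interaction fingerprints

Each of the 85 slots contributes a 7-bit block, protein perspective first:
hydrophobic, aromatic face-to-face, aromatic edge-to-face, H-bond
donor→acceptor, H-bond acceptor←donor, ionic +→−, ionic −→+; 85 × 7 = 595
bits, always. GAP slots contribute seven zeroes so fingerprints from gapped
structures remain comparable position-by-position.

Geometric rules (defaults in `ifp_config()`, all configurable):

| interaction | rule |
|---|---|
| hydrophobic | any apolar C/S pair ≤ 4.5 Å |
| aromatic F2F | ring-centroid distance ≤ 4.0 Å, inter-plane angle ≤ 30° |
| aromatic E2F | centroid ≤ 5.0 Å, angle 60–90° |
| H-bond | donor–acceptor heavy atoms ≤ 3.5 Å, donor angle ≥ 120° |
| ionic | opposite formal-charge centres ≤ 4.5 Å |

These thresholds follow common structure-based fingerprinting conventions.
Hydrogens are never required: the donor angle is evaluated at the donor
heavy atom against the mean of its heavy-atom antecedents (an idealized-H
criterion), and water donors (no heavy antecedent) pass on distance alone.
Protein atom typing is table-driven by residue and atom name; ligand typing
comes from the curated topology (below). Both H-bond direction bits may
co-fire for bifunctional groups. Aromatic rings are the smallest rings
(size 5/6) whose bonds are aromatic; fused systems decompose into their
small rings. Water-mediated contacts are deliberately *not* part of the
595 bits — they are evaluated separately in the water-cluster assignment.

Fingerprint similarity is Tanimoto over set bits, defined as 1 when both
fingerprints are empty (two apo structures are identically featureless).

## Ligand topology curation

Interaction typing is only as good as the ligand chemistry, so hetero
groups are curated before fingerprinting. If the chemical component
dictionary has an entry for the component code, bond orders, charges and
aromatic flags are taken from it, matched by atom name (a name mismatch
falls back to geometry with a warning). Otherwise bonds are perceived from
covalent radii (×1.25), short C–O pairs (< 1.28 Å) become carbonyls, and
planar 5/6-rings of C/N/S/O with mean bond length ≤ 1.46 Å become aromatic.
Protonation is rule-based at pH 7.4 — carboxylates and ≥ 2 terminal
phosphate oxygens negative, aliphatic amines and amidine/guanidine
nitrogens positive — with no pKa calculation: that is sufficient to type
ionic centres and H-bond donors/acceptors, which is all the fingerprint
needs. Curation is idempotent, and the `curated` flag records whether
anything changed.

## Conformation classes

**DFG.** Three descriptors, all computed after superposition so the frame
is fixed: the Shrake–Rupley accessible surface area of the xDFG aspartate
(slot 81; probe 1.4 Å, 960 sphere points by default, 240 in the bundled
corpus runs where convergence is within ~1%), and the y-components of
Cγ−Cα for slots 81 (yD) and 82 (yF). Classification applies a CART
decision tree (depth ≤ 3) over exactly these three descriptors. The repo
ships both the training harness (`train_dfg_tree()`, `dfg_cv_accuracy()`
with k-fold cross-validation) and a frozen JSON model
(`inst/extdata/dfg_tree.json`, regenerated by `scripts/build_models.R`);
classification is reproducible from the JSON alone. The frozen tree splits
on yD (DFG-out branch) and then yF (in vs outlike), matching the designed
geometry of the corpus.

**αC.** Thresholds on the Cα(F.xDFG.82)–Cα(E.aC.24) distance: ≤ 7.2 Å
αC-in, ≤ 9.3 Å αC-outlike, else αC-out (boundaries inclusive downward).
The master frame places the αC-in distance at ≈ 6.5 Å; the synthetic
corpus draws the three classes at shifts giving ≈ 6.1–7.0, 7.8–8.8 and
10–13 Å, and the defaults sit in the gaps between those bands. They are
config parameters, not constants, because real kinases will shift the
bands.

**G-rich loop.** Three descriptors over backbone centroids: the planar
angle at the hinge centroid between the G-loop and catalytic-loop
centroids; the G-loop–catalytic-loop centroid distance; and the rotation of
the G-loop principal axis against the catalytic-loop principal axis,
projected on the plane perpendicular to the centroid–centroid axis (sign
fixed by the chain N→C direction, so the descriptor is deterministic).
These constructions are the package's re-specification of the loop
geometry; the master-frame reference triple is frozen in the test suite.

## Subpockets and waters

The subpocket model is trained, not drawn: probes on a 0.5 Å grid
(anchored at the master-frame hinge centroid, so training is reproducible)
are scored per label by the ratio of close contacts (< 1.0 Å) with ligands
annotated for that (sub)pocket versus ligands not annotated for it. Probes
with ratio ≥ 3 are kept, best 200 per label (zero-negative probes score as
twice their positive count, so uncontested probes win). A new ligand is
flagged for a label when any heavy atom touches any retained probe
(< 1.0 Å); flags are therefore monotone in the atom set, and a post-hoc
closure enforces the hierarchy (a flagged subpocket implies its major
region). The 15 labels are the 3 major pockets and 12 subpockets; their
canonical centres in the master frame drive the synthetic corpus and are
spaced so that each label is resolvable at the probe contact radius —
overlap policy for flags is non-exclusive throughout.

Conserved waters: 13 cluster centroids (I1–I11 and the two
DFG-out-specific O1/O2) in the master frame, shipped as a versioned CSV
derived by average-linkage clustering of superposed pocket waters
(`derive_water_clusters()`; labels assigned greedily to the nearest
canonical site). A water is assigned to the nearest centroid within 1.5 Å
(ties break to the lowest label index), others are dropped, and each kept
water gets its H-bond pattern against ligand and protein with the
fingerprint module's H-bond rule.

## The synthetic fixture generator

Every stage above is exercised by fixtures built from the master frame
with known ground truth. The generator emulates the *study conditions* a
curated kinase corpus presents to the pipeline:

- conformational classes with realistic within-class spread: DFG classes
  place (yD, yF) at (+1.4, −1.3), (−1.4, +1.3) and (+1.4, +1.3) Å with
  0.15 Å jitter (side-chain coordinate precision at typical resolutions);
  in DFG-out geometries the aspartate swings into the open cleft and
  becomes solvent-exposed, so the ASA descriptor genuinely discriminates;
  αC shifts are drawn per class as described above;
- coordinate noise (Gaussian, default 0.1 Å in the labelled corpus, the
  scale of well-refined X-ray coordinates) for superposition recovery;
- designed ligand contacts: interaction groups (carbonyl, amide,
  carboxylate, ammonium, triazine-like ring, lone apolar carbon) placed
  analytically to satisfy exactly one rule each, aimed at the most open
  direction around the target residue; groups are joined by topological
  bonds and, when subpocket occupancy is requested, by fluorine marker
  atoms (fluorine participates in none of the seven rules). Every
  designed-contact fixture is verified at build time: its computed
  fingerprint must equal the designed bits exactly, so incidental contacts
  fail loudly instead of corrupting ground truth;
- gaps, side-chain truncations, point mutations, insertions, renumbering
  offsets and waters at (or off) the conserved sites.

What fixtures do **not** emulate: real side-chain rotamers, packing and
electrostatics; ligand strain and realistic chemistry (topological links
and F markers are geometric devices); crystallographic artefacts
(alternate conformations beyond simple cases, partial occupancy,
symmetry contacts); and the true diversity of kinase sequences. Green
tests therefore demonstrate that the pipeline implements its stated rules
correctly and recovers designed ground truth — not that the default
thresholds are optimal for the PDB. The independent checks in the test
suite (a brute-force all-pairs geometry oracle for the fingerprint, a
Monte-Carlo surface integrator for ASA, closed-form noise-RMSD recovery)
guard the implementations themselves.

Problem sizes in the bundled runs: 300 labelled structures for the DFG
cross-validation, 120 clouds (20% held out) for subpocket recovery, 100
replicates for noise-RMSD recovery, 200 random toy complexes for the
fingerprint oracle, chosen so the whole suite completes in a few minutes
on one core while keeping the class counts large enough for stable
percentages.

## Degenerate inputs and tie-breaks

- Alternate locations: highest occupancy wins, ties to the alphabetically
  first alt-loc code.
- More than 42 GAP slots (half the pocket): rejected as unresolved.
- Multiple orthosteric candidates: the ligand with the most pocket
  contacts (heavy atom within 4.0 Å of a front-cleft/gate-area/back-cleft
  residue) is the orthosteric ligand; the rest are allosteric. Unknown
  hetero groups default to ligand.
- Missing descriptors (GAP or truncated slots) yield class `"unknown"`
  rather than errors inside the annotation pipeline.
- Water assignment ties: lowest cluster label index.
- Query ordering: descending IFP similarity when a similarity clause
  exists, else entry id; ties entry-id lexicographic.

## Known limitations

- The bundled master profile covers the pocket positions only; using the
  package on real PDB kinase domains requires a full-domain master profile
  with the same 85-column convention.
- The Crippen-type logP is a coarse atomic-contribution estimate, adequate
  for preset filtering, not for QSAR.
- The 166 structural keys are a package-defined key set in the spirit of
  the classic structural-key fingerprints, not the licensed key
  definitions; the circular fingerprint is a hashed Morgan-style
  implementation.
- Tautomer-tolerant compound identity compares canonicalised composition,
  not full graph isomorphism; it is flagged approximate.
- Records reloaded from the JSON collection store carry descriptors and
  fingerprints but not the ligand graph, so chemical-similarity clauses
  require in-memory records.
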