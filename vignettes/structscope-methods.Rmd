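---
title: "Methods: geometric and thermodynamic triage of G-protein βγ effector complexes"
author: "structscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric and thermodynamic triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structscope)
```

## The problem

Disease variants in the G-protein β subunit — the canonical example in this
package's workflow is a leucine-to-proline substitution at position 95 of
Gβ₁, associated with GNB1 encephalopathy — can act through two distinct
structural routes: by destabilizing the β-propeller fold itself, or by
disrupting the contact surface through which the membrane-anchored Gβγ
dimer engages its effectors (GIRK potassium channels, Gα, β-ARK,
phosducin, TRPM3). Distinguishing these routes from structures alone
requires a small set of reproducible geometric and thermodynamic
operations, which this package implements as a tested pipeline:

1. **Interface detection.** A residue belongs to the interface between two
   chain groups when any of its heavy atoms lies at or below 5.5 Å from a
   heavy atom of the partner group. This is the convention popularized by
   interface-analysis servers, and the comparison is deliberately `<=`
   ("5.5 Å and below"), applied to heavy atoms only.
2. **Focal environments.** The contact list of a single residue — every
   residue with a heavy atom within the same cutoff — with exact minimum
   distances, reported separately for within-chain and cross-chain
   partners.
3. **Interaction networks.** Rule-based classification of the non-covalent
   interactions among a focal residue's environment.
4. **Point mutation.** A rigid-template side-chain substitution used to
   re-run the identical geometric stages on the mutant.
5. **Pose triage.** Membrane-geometry filtering of docked channel–Gβγ
   poses and selection of the largest-cluster and best-score cluster
   centroids.
6. **ΔΔG classification.** Thresholding of predicted stability/affinity
   changes against significance and thermal-noise levels, with conversion
   to dissociation-constant fold change.

## Residue addressing

All residues are addressed by **author numbering**: the key
`(chain, residue number, insertion code)`, written `"B:95"` or `"B:95:A"`.
This is the numbering used in the literature when a position such as "L95"
is named. mmCIF input is mapped to author numbering on read. Alternate
conformations are resolved per atom to the highest-occupancy conformer
(ties to the lexicographically smallest altloc letter), which changes the
atom set but never the residue count. Waters and hydrogens are retained on
read but flagged, and excluded from all distance computations by default;
non-water hetero groups are likewise excluded from contact counts, because
the quantities of interest are amino-acid contacts.

## Contact detection and the spatial grid

Distance between residues is the minimum heavy-atom Euclidean distance.
The neighbour search uses a uniform spatial grid with cell edge equal to
the cutoff, so any atom pair within the cutoff falls in the same or an
adjacent cell; this gives effectively linear scaling on tetramer-sized
complexes while remaining exact. Correctness is not argued — it is pinned
by tests that compare the grid search against an all-pairs brute-force
oracle on a hundred seeded fixtures, and the oracle is implemented
independently in the test code, not shared with the package.

Sequence-adjacent residues (i ± 1) are *included* in focal environments by
default, with a flag to exclude them: a contact list answers "what
surrounds this residue", and backbone neighbours are part of that answer.
Output ordering is fixed (distance ascending, then residue key) so reports
are reproducible; note that the relative order of *exactly tied* distances
is floating-point sensitive and is not part of the contract.

## Interaction typing

The interaction-network stage assigns at most one type per residue pair,
applying geometric rules in a fixed precedence order — ionic > hydrogen
bond > hydrophobic > van der Waals > generic — with conventional
thresholds:

| rule | atoms | cutoff |
|---|---|---|
| ionic | side-chain charged N of Arg/Lys (and His, optionally) vs carboxylate O of Asp/Glu | 4.0 Å |
| hbond | donor-capable N/O vs acceptor-capable N/O | 3.5 Å |
| hydrophobic | side-chain carbons of apolar residues | 5.0 Å |
| vdw | any heavy pair | Σ vdW radii + 0.5 Å |
| generic | any heavy pair | 5.5 Å |

These are conventional values, not a reproduction of any specific
annotation server's internals — published figures generated with such
servers depend on thresholds those servers do not fully document. The
design goal is therefore reproducibility of *this* rule table, which is
fully user-editable via `interaction_rules()`. Because hydrogens are
absent from crystallographic heavy-atom models, the default hydrogen-bond
rule has no angle term; His is treated as chargeable by default (flag to
disable). π–π and cation–π detection are deliberately out of scope.
Comparisons against published interaction networks should accordingly be
made at the level of contact counts, not edge types.

## The rigid-template mutant builder

`substitute_residue()` replaces one residue's side chain with an ideal
template generated from internal coordinates (standard bond lengths and
angles, trans chi dihedrals, planar rings) anchored to the residue's own
backbone frame N–CA–C via NeRF placement. Backbone atoms — and CB when
both source and target residue have one — keep their original coordinates
bit-exactly, and every other residue in the model is untouched; this is
verified by byte-level tests. The proline ring uses fixed ideal internal
coordinates and closes only approximately (CD–N ≈ 1.4–2.0 Å), and no
backbone φ adjustment is made.

**This is a deliberate simplification.** No rotamer search, repacking, or
energy minimization is performed, where a production mutagenesis protocol
would relax the structure (e.g. Rosetta-style fixed-backbone packing).
Mutant structures are labelled `*_rigid_template` and every downstream
report carries a note to that effect: wild-type/mutant contact
comparisons are *rigid-template estimates*. `clash_report()` is provided
as the corresponding sanity check, listing heavy-atom pairs below a
threshold (default 2.5 Å) around the mutated site.

## Membrane-geometry triage of docked poses

Docked poses of a channel–Gβγ complex are produced by external rigid-body
docking and consumed here as one structure file per model plus a
cluster/score table (`model_id`, `cluster_id`, `cluster_size`, `score`,
`score_type`, `is_centroid`, `path`). The triage:

1. superposes each pose onto a membrane-embedded reference by matched
   receptor Cα atoms (Kabsch least squares, implemented via the closed-form
   SVD solution and cross-checked in tests against an independent
   least-squares fit);
2. applies two conjunctive exclusion rules in the membrane frame, with the
   convention +z = extracellular: a pose is excluded if **any ligand heavy
   atom lies strictly above the lower (cytoplasmic) leaflet plane**, or if
   the **Cα of the G-gamma C-terminal residue lies strictly more than 30 Å
   below that plane**. The 30 Å bound encodes the reach of the
   geranylgeranyl anchor at the Gγ C-terminus, which tethers Gβγ to the
   inner leaflet. Distances to leaflets are signed plane distances along z
   (the leaflet is a z-plane, as in OPM-style embeddings), boundary
   strictness follows the wording of the rules ("above", "more than"), and
   the z convention is recorded in run metadata and flippable by
   configuration. Leaflet planes can be given explicitly or derived from
   OPM DUM pseudo-atom layers (mean z per layer).
3. selects from the retained records the centroid of the largest cluster
   and the centroid of the best-scoring cluster. Ties are resolved
   deterministically: a cluster-size tie by better score, a score tie by
   lower cluster id. Both rules are conjunctive, so rule order cannot
   change the retained set, only the reported reason (reported in the
   fixed order above).

Whether triage runs on all cluster members or on centroids only is left to
the caller — the functions filter whatever set they are given, and the run
metadata records what that was.

## Thermodynamic classification

With R = 1.9872042586×10⁻³ kcal·mol⁻¹·K⁻¹ and T = 298.15 K (25 °C
exactly), RT ≈ 0.5925 kcal/mol — the conventional "0.6 kcal/mol" thermal
noise scale. A predicted ΔΔG is classified on its magnitude:

* `significant` when |ΔΔG| > 1.0 kcal/mol (strictly; exactly 1.0 is not
  "larger than 1"),
* `above_noise` when 0.6 < |ΔΔG| ≤ 1.0,
* `within_noise` when |ΔΔG| ≤ 0.6.

The sign (stabilizing vs destabilizing) is preserved in a separate column
rather than folded into the class. Binding ΔΔG converts to a
dissociation-constant fold change as exp(|ΔΔG|/RT); 1 kcal/mol at 25 °C
gives ≈ 5.4, the conventional "~5-fold". The fold change is exactly
multiplicative in ΔΔG, which the tests assert to 10⁻⁹ relative. ΔΔG
values themselves are inputs (from predictors such as mCSM); predicting
them is out of scope, and the table schema carries them verbatim.

## The synthetic-fixture generators

Because the real inputs of interest are either deposited structures or
undeposited docking outputs, the package ships generators that emit small
fixtures with *planted, exactly recoverable truth*:

* `make_complex()` builds a two-chain structure in which exactly
  `n_contacts` cross-chain residue pairs sit at the requested minimum
  heavy-atom distance — by direct construction, not sampling, so the
  planted distance is exact to machine precision — and all other
  cross-chain pairs clear a background margin (default 8 Å). Chain A
  residues sit on a coarse helix with ~23 Å between consecutive residues
  so planted contacts cannot leak onto neighbours; all planted contacts
  involve a designated focal LEU, mirroring a focal-position analysis
  (the default plants 7 contacts, the motif size of interest at desk
  scale). The generator re-verifies its own geometry all-pairs before
  returning and refuses infeasible requests.
* `make_pose_ensemble()` emits a membrane-embedded reference plus a pose
  ensemble with planted verdict labels (default 30% with an atom above
  the lower leaflet, 20% with the Gγ C-terminus too deep, remainder
  passing), each pose written after a random rigid transform so triage
  must actually superpose, and a cluster table with distinct sizes and
  scores so the correct centroid selection is unambiguous.
* `make_ddg_table()` samples ΔΔG magnitudes strictly inside each class
  interval (clear of both boundaries), with random signs.

All generators are deterministic: the same seed reproduces byte-identical
files. What the fixtures deliberately do **not** emulate: real protein
fold geometry (the WD40 β-propeller), realistic side-chain packing,
crystallographic noise, or correlated docking-score structure. Passing
tests therefore demonstrate that the *operations* are exact on inputs with
known answers — not that any biological conclusion about a particular
complex is correct. Real structures enter through `read_structure()`
(PDB/mmCIF) and run through the identical code paths.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated
fixtures: 100 complexes of ≤ ~150 atoms for the grid-vs-brute-force
equivalence, ensembles of 40 poses for triage, tables of 40–60 rows for
classification — sizes at which exhaustive oracles are instant while still
exercising every code path. Distance comparisons use `<=` with a 10⁻¹²
guard against floating-point jitter in squared-distance arithmetic;
superposition requires ≥ 3 non-collinear matched Cα pairs and fails loudly
otherwise; PDB output rounds coordinates to the format's 10⁻³ Å columns,
and round-trip stability at that precision is tested.

## Known limitations

* The mutant builder is rigid; mutant contact counts near the substitution
  can over- or under-count relative to a repacked model.
* Hydrogen-bond detection has no geometric angle term by default.
* No buried-surface-area or binding-affinity regression; interface
  membership is purely distance-based.
* Multi-model (NMR-style) files contribute only their first model.
* Docking, pose clustering, ΔΔG prediction, conservation scoring and
  membrane embedding are consumed as inputs, never computed.
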