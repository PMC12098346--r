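# structscope

Geometric and thermodynamic triage of protein–protein complexes, built
around the workflow used to interpret disease mutations at G-protein
βγ–effector interfaces — the motivating case being the Leu→Pro
substitution at position 95 of Gβ₁ (a GNB1-encephalopathy variant) and
its consequences for Gβγ binding to GIRK potassium channels and other
effectors.

The package answers, reproducibly and with tests against exact oracles:

* **Which residues form the interface** between two chain groups? A
  residue is an interface member when any heavy atom lies ≤ 5.5 Å from a
  heavy atom of the partner group (the PRODIGY-style convention).
* **What surrounds a focal residue** — its ≤ 5.5 Å contact environment
  with exact minimum heavy-atom distances (an INTAA-style contact list)?
* **What non-covalent interactions** (ionic, hydrogen bond, hydrophobic,
  van der Waals, generic) connect that environment, under a documented,
  user-editable geometric rule table applied in fixed precedence?
* **What changes upon point mutation** — via a declared rigid-template
  side-chain substitution (no repacking/minimization) re-run through the
  identical stages, with the wild-type/mutant difference reported as set
  arithmetic on the two environments?
* **Which docked poses are membrane-plausible** — excluding poses with
  any Gβγ atom strictly above the lower membrane leaflet, or with the Gγ
  C-terminal Cα more than 30 Å below it (the reach of the geranylgeranyl
  anchor) — and which retained cluster centroids (largest cluster, best
  score) deserve analysis?
* **Is a predicted ΔΔG meaningful** — classified as significant
  (> 1 kcal/mol), above noise, or within thermal noise (≤ 0.6 kcal/mol
  ≈ RT at 25 °C), with conversion to a dissociation-constant fold change
  exp(|ΔΔG|/RT)?

Every stage runs on synthetic fixtures with planted, exactly recoverable
ground truth (`make_complex()`, `make_pose_ensemble()`,
`make_ddg_table()`), so the whole pipeline is testable without
downloading a single structure. Real structures enter through
`read_structure()` (PDB and mmCIF, author numbering) and run through the
same code paths.

## Worked example

```r
library(structscope)

# a synthetic complex with 7 contacts planted at 4.0 A around a focal LEU
man <- make_complex(seed = 7, n_contacts = 7)
rep <- analyze_complex(man$model, group_a = "A", group_b = "B",
                       focal = man$truth$focal,
                       mutation = mutation_spec("A", 6, "PRO",
                                                from_aa = "LEU"))
rep
#> <complex_report> synthetic_complex_s7 focal A:6
#>   interface: 1 + 7 residues, 7 contacts; focal in interface: TRUE
#>   environment WT: 7 (7 inter-chain, 0 intra-chain)
#>   environment mutant: 7; delta: 7 retained, 0 lost, 0 gained
```

The focal residue is an interface member; its environment holds exactly
the 7 planted partners at the planted distance, and a Leu→Pro
substitution that keeps the shared Cβ retains all of them (a
rigid-template estimate — the builder does not repack):

```r
head(residue_environment(man$model, man$truth$focal), 3)
#>    key chain resno icode resid min_distance same_chain
#> 1  B:8     B     8         ALA            4      FALSE
#> 2 B:10     B    10         ALA            4      FALSE
#> 3  B:2     B     2         ALA            4      FALSE
```

ΔΔG classification of two hypothetical complexes — a strongly
destabilizing mutation whose binding effect sits at the noise threshold:

```r
ddg_report(data.frame(complex_id = c("girk2_bg", "girk12_lc"),
                      mutation = "L95P",
                      ddg_stability = c(2.4, 1.8),
                      ddg_affinity = c(0.62, 0.55)))
#> <ddg_report>
#>   2 record(s), 2 classified, 0 error(s)
#>   stability: 2 significant, 0 above noise, 0 within noise
#>   affinity: 0 significant, 1 above noise, 1 within noise
#>   thresholds: significant > 1 kcal/mol, noise <= 0.6 kcal/mol; RT = 0.5925 kcal/mol at 298.15 K

rt_energy()          # 0.5925 kcal/mol at 298.15 K, the "0.6" noise scale
kd_fold_change(1.0)  # 5.41 — the "~5-fold" Kd change per 1 kcal/mol
```

Pose triage on a synthetic ensemble with planted pass/fail labels:

```r
pe  <- make_pose_ensemble(seed = 3, n_poses = 40)
ref <- read_structure(pe$paths$reference)
tri <- triage_ensemble(read_pose_table(pe$paths$pose_table),
                       pe$frame, ref, pe$criteria)
tri                       # <triage_result> 20/40 poses retained
select_models(tri$retained)[, c("model_id", "role")]
```

To analyze a real deposited complex (e.g. a GIRK2–Gβγ crystal structure
with Gβ chain B), point the same functions at the file:

```r
m <- read_structure("4kfm.pdb")
analyze_complex(m, group_a = c("B", "G"), group_b = c("A", "C", "D", "E"),
                focal = "B:95",
                mutation = mutation_spec("B", 95, "PRO", from_aa = "LEU"))
```

## Scope

Docking, pose clustering, ΔΔG prediction (mCSM-style), Rosetta-style
repacking, conservation scoring and membrane embedding are consumed as
*inputs*, never computed. See the methods vignette
(`vignettes/structscope-methods.Rmd`) for the model conventions, rule
tables, numerical choices, and known limitations.
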