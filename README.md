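# complexeval

Stoichiometry-aware evaluation of predicted macromolecular complexes, in R.

## What this is for

Modern structure predictors model whole assemblies — several protein or
nucleic-acid entities, each possibly in multiple copies, plus small-molecule
ligands — usually without knowing the true composition in advance.
Benchmarking such predictions needs machinery that single-chain evaluation
never required: scores that can either penalise or forgive missing copies,
an optimal assignment of interchangeable model chains to reference chains,
symmetry-corrected ligand pose errors, and a sequence-only notion of target
novelty for a continuously running benchmark.

`complexeval` is that engine, for people who run or study complex-prediction
benchmarks: it reads reference and model structures (mmCIF/PDB), classifies
targets as easy / medium / hard / ligand from template evidence, maps model
chains and ligands onto the reference, scores, aggregates, and reports — and
ships a deterministic synthetic-complex generator so everything is testable
offline.

## The scores

All LDDT-family scores are superposition-free fractions of preserved
reference distances. With `D` the set of heavy-atom pairs within 15 Å of
each other in the reference (same-residue pairs excluded):

    LDDT = mean over (i,j) in D of mean over t in {0.5, 1, 2, 4} Å of
           1[ |d_model(i,j) − d_ref(i,j)| ≤ t ]

Distances touching atoms absent from the model count zero — that is the
stoichiometry penalty. The family:

| score | distance set | undefined when |
|---|---|---|
| LDDT | all polymer pairs | reference has no pairs |
| iLDDT | inter-chain pairs only | monomer (no inter-chain pair) |
| mapped LDDT / iLDDT | same, reference restricted to mapped chains | empty mapping; single mapped chain |
| LDDT-PLI | polymer–ligand contacts (4 Å), best over ligand automorphisms | ligand has no polymer contact |

Undefined is reported as `NA`/`null` with a reason, never as 0.

The **TM-score** is backbone-only and superposition-based,
`max (1/L_ref) Σ 1/(1+(d_i/d0)²)` with `d0 = max(0.5, 1.24·(L_ref−15)^⅓ − 1.8)`,
maximised by iterative fragment-seeded superposition in a single global
frame. **BiSyRMSD** superposes the model on the reference binding site
(residues within 4 Å of the ligand) and reports the ligand heavy-atom RMSD
minimised over graph automorphisms; a pose is a success when BiSyRMSD
< 2.0 Å strictly, with 1 and 5 Å also reported, and unpredicted ligand
copies count as failures. Per-target ligand aggregation weights each ligand
by its heavy-atom count so ions cannot dominate.

Target difficulty uses the sequence rules (protein easy: identity ≥ 85 %,
coverage ≥ 70 %, < 45 uncovered residues beyond length 250; medium:
identity < 85 % but e-value ≤ 1e-4 with the same coverage; peptides and
nucleic acids: exact full-length match or hard) aggregated over templates,
with easy complexes upgraded to "ligand" targets when no easy template
carries the same ligand set.

## Worked example

Build a synthetic homodimer with a benzene ligand, then score a model that
predicted only one of the two chains:

```r
library(complexeval)

spec <- fixture_spec(seed = 7, n_entities = 1, copies_per_entity = 2,
                     chain_length = 30, ligands = "c1ccccc1")
fx <- make_complex(spec)
fx$reference
#> <eval_structure> synthetic [assembly 1]
#>   chain A   protein    30 residues    90 atoms
#>   chain B   protein    30 residues    90 atoms
#>   chain L1  ligand      1 residues     6 atoms

model <- make_model(fx$reference, list(type = "drop_chain", k = 1))
score_complex(model, fx$reference, fx$target)
#> <score_report> synthetic / server (model 1)
#>   LDDT 0.296  mapped 1.000  iLDDT 0.000  mapped undef  TM 0.500
#>   oligomeric state: predicted 1 / reference 2
#>   ligand LDDT-PLI (weighted) 1.000; success 1/2/5 A: 1.000 1.000 1.000
```

Reading the numbers: the single predicted chain is itself perfect, so the
**mapped** LDDT is 1.000, but every reference distance touching the missing
copy scores zero, pulling the stoichiometry-aware LDDT down to 0.296 and the
interface LDDT to 0. The mapped interface score is undefined (`undef`, not
zero) because one mapped chain has no interface. TM-score is 0.5: half the
reference backbone is reproduced exactly, half is absent. The ligand pocket
lives on the predicted chain, so the pose scores stay perfect.

The same pipeline is scriptable from a shell through the thin launcher in
`inst/cli/` (`simulate`, `score`, `classify`, `ligcat`, `summarize`
subcommands; see `?run_cli`).

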