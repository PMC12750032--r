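---
title: "Evaluating predicted macromolecular complexes with complexeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating predicted macromolecular complexes with complexeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexeval)
```

## The problem

Structure prediction has moved from single protein chains to whole
macromolecular complexes: several protein (or nucleic acid) entities, each
possibly present in multiple copies, together with small-molecule ligands.
Benchmarking predictions of such complexes raises questions that single-chain
evaluation never had to answer:

* **Stoichiometry.** At prediction time the composition of the biological
  assembly is typically unknown. A method that predicts a monomer for a
  homodimer target has made a real error, but one of a different kind than
  misfolding a chain. Scores must be able to either penalise or forgive
  missing copies, explicitly.
* **Chain ambiguity.** When an entity occurs in several copies, model chain
  labels carry no meaning; scoring requires an optimal assignment of model
  chains to reference chains.
* **Ligand symmetry.** Chemically equivalent atoms (a benzene ring, the two
  carboxylate oxygens of acetate) make naive ligand RMSDs ill-defined;
  equivalence classes of atom orderings (graph automorphisms) must be
  searched.
* **Novelty.** A continuously running benchmark must decide, from sequence
  information alone, whether an upcoming structure is a trivial, moderate,
  or hard modelling target, and whether its ligand context is new.

`complexeval` implements this evaluation engine end to end: structure I/O,
target difficulty classification, chain/ligand mapping, the score family,
aggregation and reporting — plus a deterministic synthetic-complex generator
so that every component is testable offline, without any external database.

## Scores

### LDDT

The Local Distance Difference Test is superposition-free. The reference
defines a distance set: all pairs of heavy polymer atoms within an
**inclusion radius** of 15 Å, excluding pairs within one residue. For each
reference distance $d^{ref}_{ij}$ the model distance $d^{mod}_{ij}$ is
checked against tolerance **thresholds** $\{0.5, 1, 2, 4\}$ Å and the score
is the mean over distances of the fraction of thresholds satisfied:

$$\mathrm{LDDT} = \frac{1}{|D|}\sum_{(i,j)\in D}\;\frac{1}{4}\sum_{t}
  \mathbf{1}\!\left[\,|d^{mod}_{ij}-d^{ref}_{ij}|\le t\,\right]$$

Every distance with either atom missing from the model — missing residue,
missing chain, atom removed by the stereochemistry filter — contributes 0 at
all thresholds. This is what makes LDDT *stoichiometry-aware*: a perfect
single chain against a homodimer reference loses the full weight of every
distance touching the unpredicted copy.

* **iLDDT** is the same statistic restricted to distances whose atoms lie in
  *different* polymer chains. It isolates interface accuracy and is
  **undefined** (not zero) for monomers, which have no inter-chain distance.
* **Mapped variants** recompute LDDT/iLDDT after restricting the reference
  to the chains that actually received a model partner. They remove the
  missing-copy penalty, isolating per-chain accuracy from composition
  errors. Mapped iLDDT is undefined when a single chain was mapped. The pair
  (stoichiometry-aware, mapped) is reported together precisely so that the
  two error kinds can be told apart.
* **Undefined is never zero.** All undefined scores propagate as `NA` in R
  and `null` in JSON, with a reason string. Averaging an undefined interface
  into a mean as 0 would corrupt every downstream comparison.

### TM-score

The TM-score is the complement to LDDT: backbone-only,
superposition-dependent, normalised by the reference backbone length
$L_{ref}$ with the canonical scaling constant

$$d_0 = \max\!\left(0.5,\; 1.24\,\sqrt[3]{L_{ref}-15} - 1.8\right),\qquad
\mathrm{TM} = \max_{\text{superpositions}} \frac{1}{L_{ref}}
 \sum_i \frac{1}{1 + (d_i/d_0)^2}$$

Unmapped reference residues contribute 0. The maximisation uses the standard
iterative scheme: Kabsch superposition seeded on fragments of decreasing
length (full, half, quarter, down to 4 residues at half-overlapping
offsets), each refined by re-superposing on the residues currently within
$d_0$ until the selected set stabilises. One global frame is used across
all chains, so inter-chain placement errors lower the complex TM-score.

### Ligand scores

* **LDDT-PLI** applies the LDDT threshold logic to reference
  polymer-atom/ligand-atom contacts within a **contact radius** (default
  4.0 Å, configurable; this radius is a package choice — contact-based
  interface scores conventionally use tighter radii than the 15 Å global
  inclusion radius). The ligand atom correspondence is optimised over the
  ligand's graph automorphisms, so symmetric poses are never penalised.
  Undefined when the reference ligand has no polymer contact.
* **BiSyRMSD** is the binding-site superposed, symmetry-corrected RMSD: the
  binding site is every reference polymer residue with a heavy atom within
  the **site radius** (default 4.0 Å, configurable) of the ligand; the model
  is superposed on the site backbone atoms; the ligand heavy-atom RMSD is
  minimised over automorphisms. Undefined when fewer than 3 site atoms can
  be matched. A pose is a **success** when BiSyRMSD is *strictly* below
  2.0 Å (1 and 5 Å are also reported); the success count is divided by the
  **total** number of reference ligands, so unpredicted copies are failures.
* **Weighted LDDT-PLI.** Per-target aggregation weights each ligand by its
  heavy-atom count: a structure full of single-atom ions cannot dominate
  the mean. A **best-pose-per-entity** variant keeps, for each ligand
  entity, the copy with the lowest BiSyRMSD (ties: higher LDDT-PLI), which
  deliberately does not penalise failing to predict multiple copies.

### Assembly selection

A reference entry may define several biological assemblies. Models are
scored against all of them; polymer scores are reported against the assembly
with the highest LDDT, ligand scores against the assembly scoring the most
ligands, ties broken by higher ΣLDDT-PLI, then lower ΣBiSyRMSD, then the
lowest assembly identifier — a fully deterministic cascade.

## Mapping

The objective of chain mapping is not defined by any single convention; we
document ours: among entity-compatible injective assignments (same entity
annotation, or identical derived sequence), the package maximises the
complex backbone LDDT of the candidate assignment. Assignments are
enumerated exhaustively while the combinatorial size is small (up to 6
interchangeable copies per entity, product capped at 720 complete
assignments) and otherwise seeded greedily and refined by pairwise swaps.
Equal-scoring assignments resolve to the lexicographically smallest pair
list, so outputs are reproducible. Final reported scores are recomputed
all-atom under the chosen assignment; the backbone-only objective merely
decouples assignment cost from scoring cost.

Ligand mapping assigns model ligands to graph-isomorphic reference ligands
(element-coloured graph isomorphism, bond orders ignored to stay robust
against aromatic/Kekulé dialects) maximising the summed pose score, with
unmatched reference ligands left unmapped and counted as failures.
Automorphism enumeration is VF2-based with a configurable cap (default
10,000) and a truncation flag; the identity permutation is always present.

## Target classification

Entities are typed from canonical sequences (derived from component IDs via
the bundled parent dictionary): amino-acid sequences of ≥ 30 residues are
proteins, shorter ones peptides; nucleic entities are typed by alphabet.
Sequences containing unknown or non-linking residues, components without a
dictionary parent, or mixed amino/nucleic content invalidate the target.

Per (sequence, template) pair:

* protein **easy**: identity ≥ 85 %, coverage ≥ 70 %, and for targets
  longer than 250 residues fewer than 45 uncovered residues;
* protein **medium**: identity < 85 % but e-value ≤ 10⁻⁴, same coverage
  requirements;
* otherwise **hard**. Peptides, DNA and RNA are easy only at 100 % identity
  with full coverage.

A complex is **easy** if one template covers all entities as easy,
**medium** if not easy but some template is easy-or-medium for all, and
**hard** otherwise (including when no single template covers the complex).
Easy complexes whose ligand component set matches no easy template's ligand
set are upgraded to **ligand** targets. Water (`HOH`) is excluded from the
set comparison by default — the rule's intent is novel ligand *context*, and
crystallographic water would make almost every target "novel"; the exclusion
list is configurable.

Conventions worth stating explicitly:

* The internal aligner (local alignment, BLOSUM62 for amino acids, affine
  gaps) reports identity over aligned columns; clustering identity is
  matches over the *shorter* sequence length, following the respective
  tool conventions. The internal aligner produces no e-value, so the medium
  rule is exercised through external hit tables (the 12-column tabular
  dialect), which is also how the generator emits its battery.
* Multiple local alignments (HSPs) of one query-template pair merge by
  uniting their query intervals before the coverage tests; merged identity
  is the alignment-length-weighted mean and the merged e-value the minimum.
  Union is the permissive reading; a stricter single-HSP rule would only
  relabel borderline split-alignment cases from easy/medium toward hard.
* Sequence clusters are built greedily, longest sequence first, each
  sequence joining the first cluster whose *founder* it matches at the
  threshold (99 % for proteins, 100 % otherwise). The reported
  representative of a cluster is its alphabetically first member — the
  founder governs membership, the alphabetical rule governs naming.
* Complex clustering treats the entity content as a *set* of sequence
  clusters, not a multiset: a homodimer and its monomer cluster together.
  This is the literal reading of "same set"; it merges targets differing
  only in copy number, which is also the more useful behaviour when the
  point of clustering is redundancy removal across weekly releases.

## Ligand categories

Each ligand receives exactly one of five categories, in precedence order:
**ion**, **cofactor**, **artifact** (membership in bundled, user-replaceable
component-ID lists, validated to be disjoint), then **drug-like** (passes
the Lipinski rule of five *and* occurs in fewer than 100 PDB entries),
otherwise **other** (metabolites, sugars, lipids…). The Lipinski test
defaults to the strict all-four variant (MW < 500 Da, donors ≤ 5, acceptors
≤ 10, logP ≤ 5); the classic one-violation variant is a switch. Occurrence
counts are an input table, not a live query; a small example table ships
with the package. Descriptors come from the cheminformatics backend (Open
Babel via ChemmineR) after canonicalization, so kekulized and aromatic
SMILES agree; monoatomic ions take tabulated atomic weights and zero
donors/acceptors.

## The synthetic generator

`make_complex()` builds idealized complexes: each chain is a helical trace
(2.3 Å radius, 1.5 Å rise, 100° per residue) with three heavy atoms per
residue (CA on the helix, CB radially outward, O axially offset), entity
copies placed by rigid translation 11 Å apart so that adjacent chains are
in contact but never clash. Ligands (from a small analytic geometry
library: single-atom species, water, ethanol, acetate, benzene) are placed
against a chain surface, over the local triangle of CB atoms one helical
turn apart, pushed outward until at least three residues keep an atom
within 4 Å and no polymer atom comes closer than 2 Å. Everything is
deterministic under the spec seed, to the byte in written files.

`make_model()` applies exactly one documented perturbation, each with a
known score relation: `none` (all scores perfect), whole-complex
`rigid_shift` (LDDT 1, BiSyRMSD 0 — superposition-free and site-superposed
scores ignore global placement), single-chain `rigid_shift` beyond the
largest threshold (iLDDT 0), `drop_chain` (LDDT < 1 while mapped LDDT
stays 1), `drop_ligand`, `swap_chain_labels` (scores unchanged after
mapping), `per_atom_noise` (isotropic Gaussian; for σ = 0.3 Å the distance
logic keeps LDDT above 0.9 on this geometry — the Monte-Carlo band measured
over 20 noise seeds is 0.921–0.943 without the stereochemistry filter,
which on this coarse three-atom-per-residue trace also flags some jittered
atoms and widens the band downward), and `uniform_displacement` (below).

The TM-score fixture displaces every residue by exactly *d* along unit
directions constrained to have zero sum and zero cross-covariance with the
centered CA coordinates (found by alternating projection between the linear
constraint space and the product of unit spheres). Under these constraints
the Kabsch cross-covariance matrix is symmetric positive definite, so the
optimal superposition is provably the identity and the TM-score has the
closed form $1/(1+(d/d_0)^2)$. At 150 residues this holds for the tested
displacements (1, 2, 5 Å) against the full iterative optimiser; on much
shorter chains large displacements admit better subset superpositions and
the premise (not the score) breaks down — the fixture length is part of its
definition.

`make_classification_set()` emits ≥ 40 targets spanning every rule branch —
identity at 85.0/84.9, coverage at exactly 70 %, 44/45/46 uncovered
residues on 300-mers, the 250/251 length switch, e-values at 1e-4/2e-4,
peptide exact-match cases, all complex aggregation branches, and ligand-set
matches, mismatches, multi-ligand sets and water exclusion — plus randomized
fill kept away from the 45-residue knife edge. Expected labels come from
`expected_label_literal()`, a deliberately separate, self-contained
transcription of the rules, so the test compares two independent
implementations.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real backbone geometry and side chains (only
three pseudo-atoms per residue), experimental artifacts (missing density,
altloc disorder beyond synthetic cases, B-factors), real template databases
(hits are constructed, not searched), conformational change between
template and target, and real ligand flexibility (analytic rigid
geometries). The suite validates the *scoring and rule machinery*, not
predictive difficulty of real targets.

## Numerical choices and degenerate inputs

* LDDT constants (15 Å, {0.5, 1, 2, 4} Å) are the established defaults; the
  contact radius for LDDT-PLI and the site radius for BiSyRMSD default to
  4.0 Å and are exposed in the configuration.
* The stereochemistry filter is deliberately simplified: model heavy atoms
  in different residues closer than 1.5 Å (consecutive backbone C–N
  partners exempt) or same-residue atoms closer than 0.7 Å are removed
  before scoring, so they score zero rather than contributing impossible
  geometry. Full dictionary-based bond-length/angle validation is out of
  scope; the filter is a switch (`stereo_check`).
* Alternate locations keep the highest-occupancy conformer, ties broken by
  altloc letter. Insertion codes are accepted in references (renumbered
  sequentially) and rejected in models, which must follow 1-based target
  numbering.
* Kabsch superposition guards against reflections (determinant +1
  enforced); fewer than 3 matched points is an error for superposition and
  an undefined score for TM/BiSyRMSD.
* Empty distance sets, monomer interfaces, ligands without polymer
  contacts, empty mappings: all yield `NA` with a reason, never 0.
* Reference eligibility: NMR and X-ray always qualify; EM at resolution
  ≤ 4.0 Å; complexes with > 200 polymer chains or > 100 copies of one
  entity are excluded. The rule is monotone: worsening resolution or adding
  chains can only remove eligibility.
* Server comparison restricts to the intersection of predicted target sets
  and reports means and medians per score; per-target success fractions are
  macro-averaged (per target first, then across targets).

## Problem sizes in the test suite

The suite runs on synthetic fixtures sized for exactness rather than scale:
50 random complexes of ≤ 300 atoms for the LDDT oracle comparison, a
150-residue chain for the TM closed form, 30-residue dimers for
stoichiometry cases, 20 molecules of ≤ 12 heavy atoms for the automorphism
oracle, and a 48-target classification battery. The full suite and the
acceptance script each complete in well under a minute on one CPU.

## Known limitations

* The internal aligner provides no e-value; medium-difficulty
  classification requires external hit tables (the bit-score surrogate is
  disabled by default).
* PDB output truncates chain identifiers to one character (with a
  deterministic reallocation pool); mmCIF is the primary format.
* mmCIF writing covers the `atom_site` category only.
* Oligosaccharide entities and NMR ensembles beyond the first model are out
  of scope, as are QS-score/DockQ-style interface scores and model quality
  estimate evaluation.
* The bundled component-parent and category lists cover common cases;
  production use should supply fuller dictionary extracts through the
  documented table arguments.
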