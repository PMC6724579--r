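---
title: "Models and methods behind structimm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind structimm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`structimm` classifies nonameric peptides presented by an
HLA-A2-like MHC class I groove as immunogenic or not, using features
derived from rapidly built three-dimensional models rather than from
sequence alone. This vignette is the package's own account of the models,
the numerical choices, and what the synthetic test bed does and does not
establish.

## The modeling procedure

Class I-bound nonamers adopt well-conserved extended backbone
conformations, which is what makes template threading viable: given a
groove template with a bound 9-mer, `thread()` keeps the peptide backbone
coordinates exactly, keeps side chains at unchanged positions, and rebuilds
the side chains of changed positions from ideal internal geometry
(z-matrix templates with standard bond lengths and angles; an improper
dihedral of +122.6° for C–N–CA–CB fixes L-chirality, validated in the test
suite against deposited structures). The "default rotamer" of a rebuilt
side chain is chosen deterministically: among the coarse
gauche–/gauche+/trans combinations of the first two chi angles (distal
chis trans; the two ring puckers for proline), the one whose atoms stay
farthest from the surrounding context is used. This makes threaded models
reasonable starting points without any stochastic packing.

`refine()` then runs Metropolis simulated annealing. Each sweep proposes
one rotamer swap per movable residue — all peptide residues plus groove
residues with any atom within 8 Å of the peptide — drawing coarse chi
combinations from {−60°, +60°, 180°} with ±8° jitter, plus a small number
(default 3) of rigid-body perturbations of interior peptide residues
(rotation ≤ 3°, translation ≤ 0.15 Å). A backbone proposal that would
leave a peptide-bond length more than 0.1 Å from the ideal 1.329 Å is
rejected as broken geometry; this replaces explicit loop-closure machinery
while preserving the contract that the chain stays intact. Acceptance uses
the Metropolis criterion under geometric cooling between reduced
temperatures 3.0 and 0.3 (defaults chosen so late-stage uphill acceptance
is rare), and the best-visited conformation per trajectory is returned.
Defaults are 50 sweeps and 10 independent decoys per peptide with features
averaged over the 3 lowest-energy trajectories, mirroring the protocol the
package emulates; the examples and tests use smaller, explicitly stated
configurations (typically 2–10 sweeps, 1–5 decoys) because the contracts
they check are size-independent.

Move evaluation uses delta scoring: only the interactions of the moved
atoms are recomputed (a C++ kernel), with one exact full rescore per sweep
to eliminate incremental drift. Register-shifted binding modes (a nonamer
sliding one pocket over) are outside the reachable move set; this
limitation is inherited from the threading approach itself.

## The desk energy backend

Exact reproduction of any licensed molecular-modeling energy function is a
non-goal. The built-in backend implements the same *term taxonomy* as the
Talaris2014 function with standard functional forms, so that the feature
semantics the network consumes are preserved:

* `fa_atr` / `fa_rep` — a 12-6 potential split at the pairwise minimum
  (attraction flattened at −ε below r_min; repulsion capped at 10^4 per
  pair so clashes stay finite), with a cubic switch between 5 and 6 Å.
* `fa_sol` (and intra-residue `fa_intra_rep`, `fa_intra_sol`) —
  Lazaridis–Karplus-style gaussian-exclusion desolvation; hydrophobic atom
  types (C, S) carry negative transfer free energies so burial is
  favorable, polar types positive.
* `fa_elec` — Coulomb with distance-dependent dielectric ε(r) = r over
  partial charges on backbone atoms and charged/polar side-chain groups.
* `hbond_sr_bb`, `hbond_lr_bb`, `hbond_bb_sc`, `hbond_sc` — heavy-atom
  geometric hydrogen bonds (donor–acceptor distance gaussian around 2.9 Å
  times directional cosine factors at both ends), classed by
  backbone/side-chain roles and sequence separation (≤ 4 is short-range).
* `rama`, `omega`, `fa_dun`, `p_aa_pp`, `pro_close` — knowledge-light
  torsion preferences: two smooth φ/ψ basins (helical and extended), a
  planarity penalty on ω, staggered-chi cosine terms, a small
  amino-acid-modulated φ/ψ term, and a proline ring-closure spring.
* `ref` — constant per-residue reference energies.
* `dslf_fa13` and `yhh_planarity` are registry placeholders that evaluate
  to zero in the hydrogen-free heavy-atom backend; they are kept so the
  18-term complex layout and its weights remain configurable and complete.

Nonbonded pairs within three bonds are excluded (bond graph derived from
the input geometry once per scoring context). Pairwise terms decompose
half to each participating residue; for peptide-only scoring
(`score_peptide_in_groove()`), peptide–groove interactions are attributed
fully to the peptide residue so that the per-position decomposition sums
exactly to the peptide totals. Peptide-only totals are routinely positive:
the peptide pays reference and torsion penalties that groove contacts only
partly repay — the sign convention (lower = more favorable) is unchanged.

Because the Supplementary list fixing the exact per-residue term selection
is not available, the nine per-residue terms default to the full
atomic-level subset (`fa_atr`, `fa_rep`, `fa_sol`, `fa_intra_rep`,
`fa_elec` and the four hydrogen-bond classes) — exactly the terms that are
not descriptive of particular amino acids — and the registry is
configurable. Likewise the published weighted term list contains 17 named
terms while the architecture calls for 18; the default registry adds
`fa_intra_sol` as the eighteenth, a documented, editable choice. A
TSV-import backend (`read_breakdown_tsv()`) accepts externally computed
unweighted term tables through the same `energy_breakdown` contract.

## Surface areas

`sasa()` places a fixed golden-spiral point layout (default 960 points) on
each atom's probe-expanded sphere (probe 1.4 Å, Bondi-type heavy-atom
radii) and counts points not buried inside any neighbor. No RNG is
involved, so areas are exactly reproducible, and the estimate converges as
the point count grows (240 → 960 → 3840 in the tests, against a dense
latitude–longitude quadrature oracle). Hydrophobic area is the area of
carbon and sulfur atoms — an atom-level classification; the alternative
residue-level classification would count whole side chains, and the
package deliberately uses the finer convention. United-atom radius
inflation is not applied because hydrogens are ignored throughout.

## Features and baselines

The candidate vector has 117 inputs: the 18 complex terms in registry
order, then for each position p1..p9 the nine per-residue terms plus total
and hydrophobic SASA (11 per position). A `selection_mask` names kept
complex terms and kept per-residue terms (applied uniformly across
positions); the shipped default keeps all 18 complex terms and 7 per
position — both SASA terms plus `fa_atr`, `fa_rep`, `fa_sol`, `fa_elec`,
`hbond_sc` — giving 81 inputs. The identity of the 7 surviving terms in
the original selection is not published; keeping both surface terms is
constrained by the observation that hydrophobic-surface inputs at
positions 5, 7 and 8 carried large weights, and the rest is a documented
guess that `eliminate_redundant_terms()` or a user mask can replace.

The sequence-only baselines are a flattened 20 × 9 one-hot encoding
(position-major, alphabetical one-letter order — the original row order is
unstated) and the 1 × 9 Wimley–White interface hydropathy encoding. The
packaged scale (kcal/mol, water → POPC interface, charged forms for D, E,
K, R) is the hydrophobicity currency of the whole package: negative values
mean hydrophobic.

## Network and training

The classifier is a conventional feed-forward network: 9–180 inputs, one
hidden layer of 1–10 tanh neurons, a single logistic output in (0, 1),
and one bias node per layer. The cited training tool does not publish its
internals in the source text, so the package states its choices
explicitly: binary cross-entropy loss (standard for a probability-like
output), fan-in-scaled symmetric uniform initialization, per-feature
standardization with statistics computed from the training fold only, and
the scaled-conjugate-gradient update rules (Møller's algorithm: conjugate
directions, finite-difference curvature along the search direction with
σ₀ = 5·10⁻⁵, Levenberg–Marquardt-style adjustment of the scaling parameter
from λ₀ = 5·10⁻⁷). Training stops when validation loss has not improved
for 6 consecutive epochs (or at the epoch cap), and the best-validation
snapshot is returned. All of these are configurable; none were tuned
against any reported benchmark.

Evaluation is nested 5-fold cross-validation: folds are pool-stratified
(nonbinder / self / immunogenic dealt round-robin within pools), roles
rotate so each fold serves as test and validation exactly once, and the
immunogenic minority is oversampled with replacement to exact balance in
training portions only — augmented indices can never leak into validation
or test folds, and the tests assert this. AUC is the exact rank statistic
(ties counted one half), identical to exhaustive pair enumeration. The
grid searches hidden sizes {2, 3, 4, 6, 8, 10} and optional input subsets
jointly; the configuration with the best mean test AUC is selected, and a
refit on the full corpus provides the companion "total" AUC, reported
separately from the cross-validated one.

Redundancy elimination is likewise unspecified in the available text; the
package implements a transparent two-stage rule — drop constant terms,
drop the later member of any term pair with absolute correlation above
0.95 (per-residue terms compared position-wise and dropped uniformly),
then a single backward sweep removing terms whose loss does not cost more
than 0.002 mean cross-validated AUC — all thresholds configurable, and a
precomputed mask can bypass selection entirely.

## The synthetic test bed

`make_groove_fixture()` builds two idealized antiparallel α-helices
(φ = −57°, ψ = −47°, default 30 residues each, axis separation 12.5 Å)
flanking an extended nonamer (φ = −150°, ψ = 150°, side chains
perpendicular to the helix plane). Each helix is spun about its own axis
to the deterministic orientation with the largest clearance from the
peptide, and all default rotamers are re-chosen in the assembled context,
so the fixture is clash-free enough to serve as a template. It emulates
the *contracts* of a class I groove — two flanking chains, occlusion of
the peptide, peptide–groove contacts — and none of its biochemistry: there
is no β-sheet floor, no binding pockets, no allele-specific chemistry.

`make_labeled_peptides()` draws pool membership multinomially from the
study corpus proportions (self : immunogenic : nonbinder =
2756 : 155 : 1044) by default, so stratification and oversampling face the
same imbalance as the real corpus; exact per-pool counts are available for
experiments that need them. Binder pools carry aliphatic anchors at
positions 2 and 9; the nonbinder pool is forced non-aliphatic there. The
immunogenic pool is enriched by rejection sampling under a logistic
propensity in positional hydrophobicity (coefficients 0.8, 0.6, 0.8, 0.7
at positions 4, 5, 7, 8 on the negated interface scale, intercept −0.3 —
one-time choices giving a clearly recoverable but not trivial effect,
echoing the TCR-facing-position enrichment reported for real immunogenic
peptides). Response frequencies for immunogenic records are 50 + Poisson(40),
i.e. all pass the evidence threshold of 50 used in curation.

Passing tests on this bed show that the pipeline's statistics are sound —
null label shuffles land near AUC 0.5, planted signals are recovered,
structure-derived features beat one-hot baselines when labels truly derive
from structure — not that the energy backend or the synthetic groove
predict real immunogenicity. Reproducing the published performance numbers
would require the real 3,955-peptide corpus, crystallographic templates
and the licensed scoring software, all outside this package's scope.

## Numerical choices and degenerate inputs

* Superposition is closed-form Kabsch with reflections excluded; fewer
  than three points or collinear sets raise degenerate-geometry errors.
* RMSD between model and reference defaults to the groove frame (fit on
  groove Cα, evaluate the peptide without refitting), which measures
  peptide placement *within* the groove; `frame = "peptide"` is available.
  Heavy atoms only; sequence-mismatched positions pair over their common
  atom names.
* Alternate locations resolve to the highest-occupancy copy (ties to first
  occurrence); HETATM records and hydrogens are dropped; waters and ions
  in templates are therefore ignored. The peptide chain is renumbered
  1..9 on load regardless of author numbering.
* Zero-variance features standardize with scale 1; hydrophobic fraction of
  a zero-area residue is 0; coincident atoms are scored at a 0.5 Å floor.
* Serialization of networks writes doubles with 17 significant digits, so
  a written model reloads bit-exactly.
* Problem sizes in tests and in `scripts/acceptance.R` (corpora of
  120–500 peptides, 2–10 annealing sweeps, 1–5 decoys, 120–3840 SASA
  points) are the package's chosen desk scale; every contract they check
  is size-independent.
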