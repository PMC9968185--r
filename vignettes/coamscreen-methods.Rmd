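---
title: "Screening binary co-amorphous systems: model and methods"
author: "coamscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening binary co-amorphous systems: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A co-amorphous system (COAMS) is a homogeneous single-phase amorphous
solid of two low-molecular-weight compounds — typically an active
pharmaceutical ingredient (API) plus a co-former, which may be another
API, an amino acid, an organic acid or another excipient. Co-amorphous
formulation combines the solubility advantages of the amorphous state
with better physical stability than a single amorphous drug, but only
some pairs co-amorphise, and trying candidate pairs in the lab is slow.
coamscreen implements a descriptor-based classifier that screens binary
combinations *in silico*: given two SMILES strings and a preparation
pathway, it predicts whether the pair will form a COAMS, quantifies how
far the pair sits from the model's training data, and ranks candidate
pairs by a combined uncertainty factor.

## The model

**Featurisation.** Each molecule receives a panel of 29 descriptors
(`descriptorNames()`): constitutional counts (atoms, heavy atoms,
hydrogens, heteroatoms, aromatic atoms/bonds, rings, rotatable bonds,
hydrogen-bond donors/acceptors, acidic/basic groups), topological
indices (atom-bond connectivity, topological diameter, Petitjean shape
index, vertex-adjacency information), molecular weight, Wildman–Crippen
logP, topological polar surface area, polarizability sums, an additive
van der Waals volume, the molecular-framework fraction, and a
charged-partial-surface-area family computed on a 3D conformer. A
binary system is encoded as 34 features: the 29 absolute descriptor
differences |d(API) − d(co-former)|, four donor/acceptor–acid/base
cross terms

> nAB = |nAcid(s1) − nBase(s2)|, nBA = |nBase(s1) − nAcid(s2)|,
> nHBDA = |nHBDon(s1) − nHBAcc(s2)|, nHBAD = |nHBAcc(s1) − nHBDon(s2)|,

and a preparation-pathway flag (thermodynamic = 0, kinetic = 1). The
difference features are symmetric under swapping the two substances;
the cross terms are not. For labelled data substance 1 is the API; for
API–API screening pairs the order is the enumeration order, and the
resulting cross-feature asymmetry is intrinsic to the encoding.

**Classifier.** The model is a voting ensemble of `nModels = 50`
gradient-boosted tree classifiers (18 boosting rounds, maximum depth
6, binary logistic objective). Before each member is trained the rows
are reshuffled with a member-specific seed and the last 15% of the
shuffled order is held out as that member's validation set; the member
is fitted on the remaining 85%. On new data every member votes 0 or 1
(its probability thresholded at 0.5) and the ensemble score is

> p = (positive votes) / nModels,

an exact multiple of 1/50 under the defaults. The pair is classified
COAMS when p ≥ 0.5 — the threshold is inclusive, so a split vote
counts as positive. Averaging votes over independently shuffled
members removes the strong dependence of a single boosted model on row
order, which is pronounced on corpora of a few hundred systems.

**Applicability and ranking.** Tree ensembles extrapolate poorly, so a
prediction is only trusted near the training data. For a candidate x
the package computes the Euclidean distance d(x, T) to the training
feature matrix T on the raw, unscaled features — by default to the
nearest training row (the usual applicability-domain convention), with
a centroid mode as an alternative; both are recorded in reports. For
positive predictions the uncertainty factor

> UF(x) = d(x, T) / p(x)^4

combines the two signals. Because p ∈ [0.5, 1], UF lies between d and
16d: a score just above 0.5 inflates UF sixteen-fold, pushing doubtful
positives down the ranking. Candidates are ranked by ascending UF, ties
broken by higher p and then pair name; pairs with p < 0.5 have no UF
and are excluded from the ranking.

## Descriptor definitions and numerical choices

Standard descriptors (molecular weight, Wildman–Crippen logP, Ertl
topological polar surface area, donor/acceptor counts, rotatable
bonds, aromatic and ring counts, SMARTS-based acidic/basic group
counts) are delegated to RDKit through a small python helper; their
semantics are RDKit's. The remaining descriptors are implemented in
the package:

* **ABC** — atom-bond connectivity index on the hydrogen-suppressed
  graph: the sum over bonds of sqrt((du + dv − 2)/(du dv)).
* **Diameter / TopoShapeIndex** — maximum topological eccentricity and
  the Petitjean index (D − R)/R, computed on the largest covalent
  fragment (a counter-ion would otherwise make the radius degenerate);
  both 0 for single-heavy-atom molecules.
* **VAdjMat** — 1 + log2(m) for m heavy-atom bonds (0 when m = 0).
* **fMF** — molecular-framework fraction: heavy atoms surviving
  iterative pruning of terminal atoms (rings plus linkers) divided by
  all heavy atoms; 0 for acyclic molecules.
* **apol / bpol** — sums of atomic polarizabilities over all atoms,
  and of |αi − αj| over all bonds, hydrogens included (CRC atomic
  polarizabilities).
* **Vabc** — additive van der Waals volume: Σ atomic contributions
  − 5.92·(bonds) − 14.7·(aromatic rings) − 3.8·(non-aromatic rings),
  which reproduces the literature value for benzene (~81 Å³).
* **Surface family (RNCS, RPCS, TASA, TPSA, RASA, RPSA)** — computed
  from per-atom solvent-accessible surface areas (Shrake–Rupley, Bondi
  radii, 1.4 Å probe, a fixed 240-point golden-spiral grid — fully
  deterministic) and Gasteiger partial charges. An atom is *polar*
  when |q| ≥ 0.2: TASA/TPSA are the hydrophobic/polar SASA sums, RASA
  and RPSA their fractions of the total surface (so RASA + RPSA = 1),
  and RNCS/RPCS scale the most negative (most positive) atom's surface
  by its share of the total negative (positive) charge.

Two panel names deserve a warning: `TopoPSA` is the topological (Ertl)
polar surface area, while `TPSA` is the 3D polar surface area from the
surface family — the panel deliberately carries both. The Petitjean
index is exported as `TopoShapeIndex` (no hyphen) so that feature
names stay syntactic in R and in serialized models.

**3D conformers.** Geometry-dependent descriptors need coordinates.
`embed3d()` uses seeded ETKDG distance-geometry embedding followed by
an MMFF94 cleanup: a single conformer, bit-reproducible for a fixed
(molecule, seed). Determinism was prioritised over conformer-ensemble
averaging, which would add cost and a convergence parameter without
changing the difference features much — across embedding seeds the
surface fractions typically move by well under 0.05 (this spread is
asserted in the test suite). The default seed is recorded on every
`Molecule` and in descriptor tables.

**Salts.** SMILES are processed verbatim by default, counter-ions
included, because curated corpora list salts as retrieved from the
compound databases (e.g. glycopyrronium bromide). A
`fragment = "largest"` switch strips counter-ions when a desalted
panel is wanted instead.

**Failures are loud.** A descriptor that cannot be computed (missing
element parameters, failed embedding, unparseable SMILES) aborts that
molecule's record with an error naming the descriptor and the SMILES.
Nothing is imputed: with only 29 descriptors per molecule a silently
wrong value would corrupt every derived difference feature. During
screening, a failing API is skipped with a logged reason and the run
continues.

## Dataset handling

The labelled corpus schema is one row per tested system: API and
co-former names and SMILES, a class (1 API–API, 2 API–amino-acid,
3 API–organic-acid, 4 API–other), molar ratio, preparation pathway,
binary outcome, and a stability flag. Raw preparation methods are
mapped to the thermodynamic/kinetic dichotomy with an editable lookup
table (milling and spray/freeze-drying are kinetic routes; melt and
slow-evaporation routes thermodynamic). Molar ratio is carried in the
schema but is not a model feature, matching the 34-feature encoding.

Curation applies three deterministic rules, in order, each removal
logged: (1) positive systems with no reported stability data are
dropped (an unverifiable COAMS); (2) any compound pair reported with
both outcomes is dropped entirely — case-by-case editorial judgement
about ratio- or technique-dependent outcomes was deliberately traded
for reproducibility; (3) a pair tested in many ratios/techniques is
capped at its first three records in file order. Curation is
idempotent and never increases the record count.

`splitTrainTest()` holds out test systems by repeated random sampling
until the test part mirrors the full data's class mix and positive
rate within ±10 percentage points (at most 10,000 attempts, then an
error suggesting a looser tolerance). `testFraction` is interpreted as
the ratio of test to training rows — round(n·f/(1+f)) test rows — so
the default 1/12 sends a 244-system corpus to 19 test and 225 training
systems; a plain fraction-of-total reading cannot produce that pair.

## The synthetic generator

No public labelled corpus ships with the package, so validation runs
on synthetic data from `generateSyntheticDataset()`. It samples
systems from a built-in library of 46 real drug-like molecules (16
APIs, 12 amino acids, 10 organic acids, 8 other excipients) with a
class mix of 31/40/20/9% and assigns labels by a planted rule on the
system's true pair features, flipped with probability `noiseRate`.

The default rule mirrors the direction a trained screening model is
expected to report: COAMS iff diff_RASA ≤ t1 (similar hydrophobic
surface fractions) and diff_nRot ≥ t2 (dissimilar flexibility).
Thresholds are calibrated per draw — the discrete feature by its
quantile (0.20), the continuous feature by matching a 68% target
positive rate, the positive share typical of curated co-amorphisation
corpora — and are stored in the returned rule object, so labels can be
re-derived exactly. At zero noise the whole pipeline must therefore
reach near-perfect held-out accuracy, and at 5% noise the package's
own acceptance bar is ≥ 0.9 held-out accuracy with both planted
features flagged important; both properties are exercised in the test
suite at n = 200–244, sizes chosen to mirror the corpus scale the
model is intended for.

What the generator does *not* emulate: literature corpora have
correlated, non-random co-former panels (a few popular amino acids
dominate), label noise that is systematic rather than independent
(technique-dependent outcomes), and a richer decision boundary than
two thresholds. Passing the recovery test shows the pipeline can learn
a low-dimensional rule through the full descriptor/feature machinery
at realistic noise — it does not certify accuracy on real corpora.

## Model selection and diagnostics

`gridSearch()` scores every hyper-parameter combination by mean member
validation accuracy, breaking ties toward fewer estimators, then
shallower trees. `compareMethods()` benchmarks the gradient-boosted
ensemble against random forest, an RBF support-vector machine (library
defaults; no grid) and k-nearest-neighbours; the KNN path min–max
scales features to [0, 1] with ranges fitted on each member's training
rows only, since nearest-neighbour distances are scale-sensitive while
tree methods are scale-invariant. Because "training accuracy" is
ambiguous for a voting ensemble, the table reports both the combined
vote's accuracy on all training rows and the mean member accuracy on
the same rows, alongside the validation figure.

`featureImportance()` retrains the entire ensemble (default 10 times,
fresh master seeds), averages each member's normalised gain importance
— the split-quality improvement each feature contributes, weighted by
covered observations, summing to 1 per member — over the 50 members,
and reports the mean ± SD per feature across repetitions. A feature
is flagged important above 1/34 ≈ 0.029, the share every feature would
have under equal contribution. Averaging over repetitions matters:
importance on small corpora is sensitive to row order, and a single
run can materially re-rank features.

## Determinism and seeds

Every stochastic step is seeded: member seeds fan out from
`masterSeed` via a fixed linear-congruential mix (so growing the
ensemble never changes earlier members), the split sampler and the
generator take explicit seeds, gradient boosting runs single-threaded,
and 3D embedding is seeded distance geometry. Identical inputs,
configuration and seeds reproduce reports byte for byte; the test
suite asserts this end to end.

## Known limitations

* Descriptor values are faithful to the stated definitions but not
  numerically interchangeable with other descriptor packages —
  surface-area and shape descriptors in particular vary across
  implementations (charge model, radii, probe, conformer). Models and
  distances must therefore always be used with descriptors from this
  package, which is why the ensemble bundle freezes the feature order
  and retains the training matrix.
* The applicability distance treats all 34 raw features equally, so
  large-magnitude features (e.g. volume, surface areas) dominate d;
  this matches the convention of reporting distances on raw
  heterogeneous units, but makes d incomparable across feature
  panels.
* UF ranks only positive predictions; a pair with p < 0.5 is reported
  but never ranked, however close to the training data it sits.
* The four-class balance and 68% positive rate are emulation targets
  for the synthetic corpus, not guarantees about any real literature
  corpus a user supplies.
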