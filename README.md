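# coamscreen

Descriptor-based screening of binary co-amorphous systems (COAMS).

A co-amorphous system is a single-phase amorphous solid of two small
molecules — an active pharmaceutical ingredient (API) combined with a
co-former (another API, an amino acid, an organic acid, or another
excipient) — that couples the solubility benefits of the amorphous
state with acceptable physical stability. Whether a given pair
co-amorphises is hard to anticipate, and lab screening of pair
libraries is expensive. coamscreen is for formulation scientists who
want to triage candidate pairs computationally before milling or
melt-quenching anything.

## The model in brief

* Each molecule (from its SMILES) gets a 29-descriptor panel: counts
  (atoms, donors/acceptors, acidic/basic groups, rotatable bonds,
  rings), topology (ABC index, diameter, Petitjean shape index),
  MW, SLogP, polar surface areas, polarizabilities, van der Waals
  volume, framework fraction, and charged-partial-surface-area terms
  from a seeded 3D conformer.
* A binary system becomes 34 features: the 29 absolute differences
  |d₁ − d₂|, four cross terms (nAB = |nAcid₁ − nBase₂|, nBA, nHBDA,
  nHBAD), and a preparation-pathway flag (thermodynamic = 0,
  kinetic = 1).
* The classifier is a voting ensemble of 50 gradient-boosted tree
  models (18 rounds, depth 6), each trained on its own random 85/15
  shuffle-split of the training systems. Members vote 0/1; the score
  p is the vote fraction (a multiple of 1/50) and p ≥ 0.5 means
  predicted COAMS.
* Predictions are only trusted near the training data: each candidate
  gets the Euclidean distance d to the nearest training row, and
  positive predictions are ranked by the uncertainty factor
  **UF = d / p⁴** (lower is better; p close to 0.5 inflates UF up to
  16-fold).

## Worked example

Train on a synthetic labelled corpus (the package ships a generator
with a planted labelling rule standing in for a literature corpus) and
evaluate on held-out systems:

```r
library(coamscreen)

ds  <- generateSyntheticDataset(200, noiseRate = 0.05, seed = 11)
cur <- curateDataset(ds)
cur
#> CoamsDataset: 196 systems (curated)
#>   labels: 133 COAMS / 63 non-COAMS
#>   classes: 1: 67, 2: 87, 3: 33, 4: 9
#>   provenance: 4 curation removals

sp   <- splitTrainTest(cur, seed = 3)        # 180 train / 16 test
fmTr <- featureMatrix(sp$train, attr(ds, "descriptorCache"))
fmTe <- featureMatrix(sp$test,  attr(ds, "descriptorCache"))

ens <- trainEnsemble(fmTr$x, fmTr$y, trainingConfig(masterSeed = 5))
ens
#> CoamsEnsemble: 50 x gradient_boosted_trees
#>   trained on 180 systems x 34 features
#>   mean member validation accuracy: 0.950

evaluateEnsemble(ens, fmTe$x, fmTe$y)$accuracy
#> [1] 1

featureImportance(fmTr$x, fmTr$y, trainingConfig(masterSeed = 5))
#> ImportanceReport: 10 repetitions, threshold 0.029 (1/34)
#>   2 feature(s) above threshold:
#>     diff_RASA              0.630 +/- 0.006
#>     diff_nRot              0.270 +/- 0.005
```

The two flagged features are exactly the ones the generator's planted
rule uses, and the mean member validation accuracy (0.950) is read off
the fifty 15% holdouts. Screening then ranks all pairs of an API list
by UF:

```r
apis <- read.csv(system.file("extdata", "example_apis.csv",
                             package = "coamscreen"))
res <- screenPairs(apis, ens, techniques = "kinetic", seed = 4)
head(res[, c("api1_name", "api2_name", "p", "d", "uf", "rank")], 3)
#>      api1_name    api2_name p      d     uf rank
#> 1 theophylline pyrazinamide 1  3.549  3.549    1
#> 2     caffeine    isoniazid 1 11.332 11.332    2
#> 3   salbutamol pyrazinamide 1 14.659 14.659    3
```

A small distance means a very similar pair sits in the training
corpus (a distance of exactly 0 would be a training pair itself);
large d flags extrapolation and inflates UF. `runReport()`
writes the full table, a top-k list and a score-vs-distance scatter
table as CSV. A command-line front end with `train`, `evaluate`,
`screen`, `importance`, `benchmark` and `make-fixtures` subcommands is
installed at `inst/scripts/coams.R`.

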