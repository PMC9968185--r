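# Shared fixtures, computed lazily and cached for the whole test run.
# Chemistry-backed fixtures go through the RDKit backend once; model
# tests that need no chemistry use the pure-numeric toy matrix below.

.fixtureEnv <- new.env(parent = emptyenv())

.memo <- function(key, fn) {
  if (!exists(key, envir = .fixtureEnv))
    assign(key, fn(), envir = .fixtureEnv)
  get(key, envir = .fixtureEnv)
}

# descriptor table for a handful of reference molecules
fixtureDescriptors <- function() {
  .memo("descriptors", function() {
    descriptorTable(c(
      methane = "C",
      benzene = "c1ccccc1",
      ethanol = "CCO",
      ibuprofen = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
      glyco_salt = "CC[N+]1(C)CCC(C1)OC(=O)C(O)(c1ccccc1)C1CCCC1.[Br-]"
    ), seed = 7L)
  })
}

fixtureDescriptor <- function(name) {
  tab <- fixtureDescriptors()
  v <- as.numeric(tab[tab$name == name, descriptorNames()])
  names(v) <- descriptorNames()
  v
}

# small zero-noise synthetic dataset (with descriptor cache attached)
fixtureDataset <- function() {
  .memo("dataset", function()
    generateSyntheticDataset(120, noiseRate = 0, seed = 42L))
}

fixtureFeatures <- function() {
  .memo("features", function() {
    ds <- fixtureDataset()
    featureMatrix(ds, attr(ds, "descriptorCache"))
  })
}

# pure-numeric toy problem: 34 named feature columns, labels from a
# separable two-feature threshold rule; no chemistry involved
toyMatrix <- function(n = 150L, seed = 1L, noise = 0) {
  set.seed(seed)
  x <- matrix(runif(n * 34L), nrow = n,
              dimnames = list(NULL, pairFeatureNames()))
  x[, "prep_flag"] <- sample(0:1, n, replace = TRUE)
  x[, "diff_nAcid"] <- 0  # a constant column, useful for importance
  y <- as.integer(x[, "diff_RASA"] <= 0.7 & x[, "diff_nRot"] >= 0.25)
  flip <- runif(n) < noise
  y <- as.integer(ifelse(flip, 1L - y, y))
  list(x = x, y = y)
}

# random record table in the canonical schema (no chemistry; for split
# and curation arithmetic)
fakeRecords <- function(n, seed = 1L,
                        classProbs = c(0.31, 0.40, 0.20, 0.09),
                        positive = 0.68) {
  set.seed(seed)
  data.frame(
    api_name = paste0("api", seq_len(n)),
    api_smiles = rep("C", n),
    coformer_name = paste0("cof", seq_len(n)),
    coformer_smiles = rep("CC", n),
    coams_class = sample.int(4L, n, replace = TRUE, prob = classProbs),
    molar_ratio = rep("1:1", n),
    prep_technique = sample(c("thermodynamic", "kinetic"), n,
                            replace = TRUE),
    label = as.integer(runif(n) < positive),
    stability_reported = rep(TRUE, n),
    stringsAsFactors = FALSE)
}
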