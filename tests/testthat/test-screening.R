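test_that("pair enumeration follows n(n-1)/2 (+n with self-pairs)", {
  apis3 <- data.frame(name = c("a", "b", "c"),
                      smiles = c("C", "CC", "CCC"))
  expect_equal(nrow(enumeratePairs(apis3)), 3)
  apis35 <- data.frame(name = paste0("api", 1:35), smiles = "C")
  expect_equal(nrow(enumeratePairs(apis35)), 595)  # C(35, 2)
  apis2 <- apis3[1:2, ]
  expect_equal(nrow(enumeratePairs(apis2, includeSelf = TRUE)), 3)
  dup <- data.frame(name = c("a", "a"), smiles = c("C", "CC"))
  expect_error(enumeratePairs(dup), "duplicate")
  expect_error(enumeratePairs(apis3[1, , drop = FALSE]), "two APIs")
})

trainedFixture <- function() {
  .memo("trainedEnsemble", function() {
    fm <- fixtureFeatures()
    trainEnsemble(fm$x, fm$y, trainingConfig(nModels = 10,
                                             masterSeed = 19))
  })
}

test_that("screening scores every pair once per technique", {
  ens <- trainedFixture()
  lib <- compoundLibrary()
  apis <- lib[lib$name %in% c("isoniazid", "pyrazinamide",
                              "ethambutol"), c("name", "smiles")]
  res <- screenPairs(apis, ens, techniques = "kinetic", seed = 42)
  expect_equal(nrow(res), 3)
  expect_true(all(res$prep_technique == "kinetic"))
  expect_true(all(is.na(res$uf) == (res$p < 0.5)))
  expect_true(all(res$d >= 0))
  both <- screenPairs(apis, ens,
                      techniques = c("thermodynamic", "kinetic"),
                      seed = 42)
  expect_equal(nrow(both), 6)
  expect_equal(nrow(unique(both[, c("api1_name", "api2_name",
                                    "prep_technique")])), 6)
})

test_that("a pair that sits in the training set has distance zero", {
  ens <- trainedFixture()
  # reconstruct a training row's features as a screening candidate
  x <- trainingMatrix(ens)[4, ]
  expect_equal(distanceToTraining(x, ens), 0)
  p <- predictScore(ens, x)
  if (p >= 0.5) expect_equal(uncertaintyFactor(0, p), 0)
})

test_that("a failing API is skipped with a reason; the run continues", {
  ens <- trainedFixture()
  apis <- data.frame(
    name = c("good1", "good2", "bad"),
    smiles = c("CCO", "CCN", "not_a_smiles"),
    stringsAsFactors = FALSE)
  res <- screenPairs(apis, ens, seed = 1)
  expect_equal(nrow(res), 1)  # only good1-good2 remains
  sk <- attr(res, "skipped")
  expect_equal(sk$name, "bad")
  expect_match(sk$reason, "SMILES")
})

test_that("reports are written, ranked and size-limited", {
  ens <- trainedFixture()
  lib <- compoundLibrary()
  apis <- lib[lib$name %in% c("isoniazid", "pyrazinamide",
                              "ethambutol", "theophylline"),
              c("name", "smiles")]
  res <- screenPairs(apis, ens, seed = 42)
  dir <- tempfile()
  nRanked <- sum(!is.na(res$rank))
  paths <- NULL
  if (nRanked >= 2) {
    paths <- runReport(res, topK = 2, dir = dir)
    top <- read.csv(paths$top)
    expect_equal(nrow(top), 2)
    expect_true(!is.unsorted(top$uf))
  }
  expect_warning(paths <- runReport(res, topK = 1000, dir = dir),
                 "exceeds")
  full <- read.csv(file.path(dir, "screening_full.csv"))
  expect_equal(nrow(full), nrow(res))
  scatter <- read.csv(file.path(dir, "score_vs_distance.csv"))
  expect_identical(names(scatter),
                   c("api1_name", "api2_name", "prep_technique",
                     "p", "d"))
})

test_that("screening is deterministic end-to-end", {
  ens <- trainedFixture()
  lib <- compoundLibrary()
  apis <- lib[lib$name %in% c("isoniazid", "ethambutol",
                              "salbutamol"), c("name", "smiles")]
  r1 <- screenPairs(apis, ens, seed = 5)
  r2 <- screenPairs(apis, ens, seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  suppressWarnings({
    runReport(r1, topK = nrow(r1), dir = d1)
    runReport(r2, topK = nrow(r2), dir = d2)
  })
  for (f in c("screening_full.csv", "screening_top.csv",
              "score_vs_distance.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
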