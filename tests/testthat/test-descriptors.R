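test_that("the panel has exactly the 29 canonical descriptors", {
  expect_length(descriptorNames(), 29)
  tab <- fixtureDescriptors()
  expect_identical(setdiff(names(tab), c("name", "smiles")),
                   descriptorNames())
  expect_true(all(is.finite(as.matrix(tab[, descriptorNames()]))))
})

test_that("methane has no countable substructures", {
  d <- fixtureDescriptor("methane")
  zero <- c("nAcid", "nBase", "nAromAtom", "nAromBond", "naRing",
            "nRot", "nHetero", "nHBDon", "nHBAcc")
  expect_equal(unname(d[zero]), rep(0, length(zero)))
  expect_equal(unname(d["nAtom"]), 5)
  expect_gt(d[["MW"]], 0)
})

test_that("benzene matches hand-counted graph descriptors", {
  d <- fixtureDescriptor("benzene")
  expect_equal(unname(d[c("nAromAtom", "nAromBond", "naRing", "nH",
                          "nHeavyAtom", "nAtom")]),
               c(6, 6, 1, 6, 6, 12))
  # ABC index: 6 ring bonds, all degrees 2 -> 6 * sqrt(2/4)
  expect_equal(d[["ABC"]], 6 * sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(d[["Diameter"]], 3)          # para positions
  expect_equal(d[["TopoShapeIndex"]], 0)    # diameter == radius
  expect_equal(d[["VAdjMat"]], 1 + log2(6))
  expect_equal(d[["fMF"]], 1)               # all atoms in the ring
  # Zhao-type additive vdW volume, literature value ~81.1 A^3
  expect_equal(d[["Vabc"]], 81.1, tolerance = 0.01)
})

test_that("ethanol hetero/donor/acceptor counts match the oracle", {
  d <- fixtureDescriptor("ethanol")
  expect_equal(unname(d[c("nHetero", "nHBDon", "nHBAcc")]), c(1, 1, 1))
})

test_that("atom-count identities hold across the fixture molecules", {
  tab <- fixtureDescriptors()
  expect_equal(tab$nAtom, tab$nHeavyAtom + tab$nH)
  # nHetero = heavy atoms minus carbons, via an independent parse
  for (i in seq_len(nrow(tab))) {
    mol <- parseSmiles(tab$smiles[i])
    nC <- sum(mol@atoms$element == "C")
    expect_equal(tab$nHetero[i], tab$nHeavyAtom[i] - nC)
  }
  # count descriptors are non-negative integers
  cnt <- c("nAcid", "nBase", "nAromAtom", "nAromBond", "nAtom",
           "nHeavyAtom", "nHetero", "nH", "nRot", "naRing", "nHBAcc",
           "nHBDon")
  m <- as.matrix(tab[, cnt])
  expect_true(all(m >= 0 & m == round(m)))
})

test_that("surface fractions are complementary and within [0, 1]", {
  tab <- fixtureDescriptors()
  expect_true(all(tab$RASA >= 0 & tab$RASA <= 1))
  expect_true(all(tab$RPSA >= 0 & tab$RPSA <= 1))
  expect_equal(tab$RASA + tab$RPSA, rep(1, nrow(tab)))
  expect_equal(tab$TASA + tab$TPSA > 0, rep(TRUE, nrow(tab)))
})

test_that("descriptors are bit-stable for a fixed SMILES and seed", {
  d1 <- computeDescriptors("CCO", seed = 7L)
  d2 <- computeDescriptors("CCO", seed = 7L)
  expect_identical(d1, d2)
})

test_that("surface descriptors agree across embedding seeds", {
  rasa <- vapply(1:5, function(s)
    computeDescriptors("CCO", seed = s)[["RASA"]], numeric(1))
  expect_lt(max(rasa) - min(rasa), 0.05)
})

test_that("salt SMILES are computed in full, or reduced on request", {
  full <- fixtureDescriptor("glyco_salt")
  expect_equal(full[["nAcid"]], 1)  # the bromide counter-ion
  tab <- descriptorTable(
    data.frame(name = "glyco",
               smiles = "CC[N+]1(C)CCC(C1)OC(=O)C(O)(c1ccccc1)C1CCCC1.[Br-]"),
    fragment = "largest")
  expect_equal(tab$nAcid, 0)
  expect_lt(tab$MW, full[["MW"]])
})

test_that("unembedded molecules are rejected for surface descriptors", {
  expect_error(computeDescriptors(parseSmiles("CCO")), "embed3d")
})
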