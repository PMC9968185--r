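test_that("a single member separates separable data and is deterministic", {
  toy <- toyMatrix(n = 120, seed = 3, noise = 0)
  fit <- trainSingle(toy$x, toy$y, trainingConfig(), memberSeed = 77L)
  expect_equal(fit$valAccuracy, 1.0)
  fit2 <- trainSingle(toy$x, toy$y, trainingConfig(), memberSeed = 77L)
  expect_identical(fit$valIndex, fit2$valIndex)
  expect_identical(fit$valAccuracy, fit2$valAccuracy)
  # holdout is ceil(15%) of the rows
  expect_length(fit$valIndex, ceiling(0.15 * 120))
})

test_that("permuted labels drop member validation accuracy to chance", {
  toy <- toyMatrix(n = 160, seed = 5, noise = 0)
  set.seed(99)
  yPerm <- sample(toy$y)
  cfg <- trainingConfig(nModels = 50, masterSeed = 21)
  ens <- trainEnsemble(toy$x, yPerm, cfg)
  majority <- max(mean(yPerm), 1 - mean(yPerm))
  expect_lt(abs(mean(memberValAccuracy(ens)) - majority), 0.1)
})

test_that("ensemble scores are exact multiples of 1/nModels", {
  toy <- toyMatrix(n = 100, seed = 8, noise = 0.3)  # noisy: mixed votes
  ens <- trainEnsemble(toy$x, toy$y, trainingConfig(nModels = 50,
                                                    masterSeed = 4))
  p <- predictScore(ens, toy$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p * 50, round(p * 50), tolerance = 1e-12)
})

test_that("an ensemble of one degenerates to a single 0/1 classifier", {
  toy <- toyMatrix(n = 60, seed = 2, noise = 0)
  ens <- trainEnsemble(toy$x, toy$y, trainingConfig(nModels = 1,
                                                    masterSeed = 2))
  expect_length(ens@members, 1)
  p <- predictScore(ens, toy$x)
  expect_true(all(p %in% c(0, 1)))
})

test_that("classification threshold is inclusive at 0.5", {
  expect_identical(classifyScore(c(0.5, 0.49, 1.0, 0)),
                   c("COAMS", "non-COAMS", "COAMS", "non-COAMS"))
})

test_that("training is reproducible end-to-end for a fixed master seed", {
  toy <- toyMatrix(n = 90, seed = 6, noise = 0.1)
  cfg <- trainingConfig(nModels = 8, masterSeed = 31)
  e1 <- trainEnsemble(toy$x, toy$y, cfg)
  e2 <- trainEnsemble(toy$x, toy$y, cfg)
  expect_identical(predictScore(e1, toy$x), predictScore(e2, toy$x))
  expect_identical(memberValAccuracy(e1), memberValAccuracy(e2))
})

test_that("evaluate counts exactly, against a brute-force tally", {
  toy <- toyMatrix(n = 80, seed = 12, noise = 0.2)
  ens <- trainEnsemble(toy$x, toy$y, trainingConfig(nModels = 10,
                                                    masterSeed = 7))
  ev <- evaluateEnsemble(ens, toy$x, toy$y)
  pred <- as.integer(predictScore(ens, toy$x) >= 0.5)
  tally <- matrix(0L, 2, 2)
  for (i in seq_along(pred))
    tally[toy$y[i] + 1L, pred[i] + 1L] <-
      tally[toy$y[i] + 1L, pred[i] + 1L] + 1L
  expect_equal(unclass(ev$confusion), tally, ignore_attr = TRUE)
  expect_equal(ev$accuracy, sum(diag(tally)) / sum(tally))
  expect_error(evaluateEnsemble(ens, toy$x[0, , drop = FALSE],
                                integer(0)), "empty")
})

test_that("column mismatches are rejected with a listing", {
  toy <- toyMatrix(n = 60, seed = 1)
  ens <- trainEnsemble(toy$x, toy$y, trainingConfig(nModels = 2))
  bad <- toy$x[1:3, -1]
  expect_error(predictScore(ens, bad), "diff_ABC")
})

test_that("member seeds are stable under ensemble growth", {
  s10 <- vapply(1:10, function(i)
    coamscreen:::.memberSeed(42L, i), numeric(1))
  s50 <- vapply(1:50, function(i)
    coamscreen:::.memberSeed(42L, i), numeric(1))
  expect_identical(s10, s50[1:10])
  expect_true(all(s50 >= 0 & s50 < 2^31))
})

test_that("probability voting is available as a config switch", {
  toy <- toyMatrix(n = 80, seed = 14, noise = 0.25)
  cfgB <- trainingConfig(nModels = 5, masterSeed = 3)
  cfgP <- trainingConfig(nModels = 5, masterSeed = 3,
                         vote = "probability")
  pB <- predictScore(trainEnsemble(toy$x, toy$y, cfgB), toy$x)
  pP <- predictScore(trainEnsemble(toy$x, toy$y, cfgP), toy$x)
  expect_true(all(pB * 5 == round(pB * 5)))
  expect_false(all(pP * 5 == round(pP * 5)))
})
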