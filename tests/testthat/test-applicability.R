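mk34 <- function(v) {
  m <- matrix(v, ncol = 34, byrow = TRUE,
              dimnames = list(NULL, pairFeatureNames()))
  m
}

test_that("distance identities: membership and 3-4-5", {
  train <- mk34(runif(34 * 6))
  x <- train[3, ]
  expect_equal(distanceToTraining(x, train, "nearest"), 0)
  origin <- mk34(rep(0, 34))
  x2 <- rep(0, 34); names(x2) <- pairFeatureNames()
  x2[5] <- 3; x2[12] <- 4
  expect_equal(distanceToTraining(x2, origin), 5)
  expect_equal(distanceToTraining(x2, origin, "centroid"), 5)
})

test_that("nearest-mode distance equals the brute-force oracle", {
  set.seed(123)
  for (rep in 1:5) {
    train <- mk34(rnorm(34 * 20))
    x <- mk34(rnorm(34 * 3))
    got <- distanceToTraining(x, train)
    brute <- apply(x, 1, function(xi)
      min(apply(train, 1, function(t) sqrt(sum((xi - t)^2)))))
    expect_equal(got, brute, tolerance = 1e-10)
  }
})

test_that("nearest never exceeds centroid plus max spoke", {
  set.seed(5)
  train <- mk34(rnorm(34 * 15))
  ctr <- colMeans(train)
  spoke <- max(sqrt(rowSums(sweep(train, 2, ctr)^2)))
  x <- mk34(rnorm(34 * 10) * 3)
  dN <- distanceToTraining(x, train, "nearest")
  dC <- distanceToTraining(x, train, "centroid")
  expect_true(all(dN <= dC + spoke + 1e-10))
})

test_that("the uncertainty factor is d / p^4 with its domain enforced", {
  expect_equal(uncertaintyFactor(0, 0.7), 0)
  expect_equal(uncertaintyFactor(411.0, 1), 411.0)
  expect_equal(uncertaintyFactor(74.2, 0.98), 74.2 / 0.98^4)
  expect_equal(uncertaintyFactor(74.2, 0.98), 80.45, tolerance = 1e-3)
  expect_error(uncertaintyFactor(10, 0.49), "positive predictions")
  expect_error(uncertaintyFactor(-1, 0.8), "non-negative")
})

test_that("UF is monotone in d and p, and bounded in [d, 16d]", {
  d <- seq(0.5, 400, length.out = 25)
  p <- seq(0.5, 1, length.out = 25)
  # increasing in d at fixed p
  for (pp in c(0.5, 0.75, 1))
    expect_true(all(diff(uncertaintyFactor(d, pp)) > 0))
  # decreasing in p at fixed d
  for (dd in c(1, 74.2, 411))
    expect_true(all(diff(uncertaintyFactor(dd, p)) < 0))
  set.seed(42)
  dr <- runif(200, 0, 500); pr <- runif(200, 0.5, 1)
  uf <- uncertaintyFactor(dr, pr)
  expect_true(all(uf >= dr - 1e-12))
  expect_true(all(uf <= 16 * dr + 1e-9))
})

test_that("ranking drops negatives, sorts by UF and is order-invariant", {
  sc <- data.frame(
    pair = c("b-c", "a-b", "a-c", "a-d", "b-d"),
    p = c(0.4, 1.0, 0.5, 0.98, 0.98),
    d = c(10, 8, 8, 74.2, 74.2))
  sc$uf <- ifelse(sc$p >= 0.5, sc$d / sc$p^4, NA)
  r <- rankCandidates(sc)
  expect_equal(nrow(r), 4)            # p = 0.4 excluded
  expect_false("b-c" %in% r$pair)
  # equal d, p = 1 vs p = 0.5: UF differs by the factor 16
  expect_equal(r$pair[1], "a-b")
  expect_equal(r$uf[r$pair == "a-c"] / r$uf[r$pair == "a-b"], 16)
  # tie on uf between a-d and b-d: lexicographic pair name
  expect_lt(which(r$pair == "a-d"), which(r$pair == "b-d"))
  set.seed(1)
  r2 <- rankCandidates(sc[sample(nrow(sc)), ])
  expect_identical(r$pair, r2$pair)
  expect_identical(r$rank, r2$rank)
})

test_that("an all-negative candidate set ranks to an empty table", {
  sc <- data.frame(pair = "x-y", p = 0.3, d = 5, uf = NA_real_)
  expect_equal(nrow(rankCandidates(sc)), 0)
})
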