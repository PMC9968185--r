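writeDatasetCsv <- function(df) {
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  p
}

test_that("reading a well-formed CSV conserves rows and maps techniques", {
  df <- fakeRecords(3)
  df$prep_technique <- c("milling", "melt-quench", "kinetic")
  got <- readDataset(writeDatasetCsv(df))
  expect_equal(nrow(got), 3)
  expect_identical(got$prep_technique,
                   c("kinetic", "thermodynamic", "kinetic"))
})

test_that("schema and value violations are explicit errors", {
  df <- fakeRecords(3)
  expect_error(readDataset(writeDatasetCsv(df[, -8])), "label")
  df2 <- fakeRecords(3)
  df2$prep_technique[2] <- "spraydrying"  # unmapped raw name
  expect_error(readDataset(writeDatasetCsv(df2)), "row\\(s\\) 2")
})

test_that("curation applies the three rules in order", {
  # 10 rows: a 4x duplicated pair (all COAMS), a contradictory pair,
  # a no-stability COAMS, and three clean rows
  df <- fakeRecords(10)
  df$api_name <- c(rep("A", 4), "B", "B", "C", "D", "E", "F")
  df$coformer_name <- c(rep("x", 4), "y", "y", "z", "w", "v", "u")
  df$label <- c(1L, 1L, 1L, 1L, 1L, 0L, 1L, 0L, 1L, 1L)
  df$stability_reported <- c(rep(TRUE, 6), FALSE, TRUE, TRUE, TRUE)
  cur <- curateDataset(df)
  r <- records(cur)
  # A-x truncated to 3; B-y dropped (contradiction); C-z dropped
  # (no stability); D-w, E-v, F-u survive
  expect_equal(nrow(r), 6)
  expect_equal(sum(r$api_name == "A"), 3)
  expect_false(any(r$api_name == "B"))
  expect_false(any(r$api_name == "C"))
  prov <- provenance(cur)
  expect_setequal(unique(prov$rule),
                  c("no_stability", "contradictory_labels",
                    "max_three_per_pair"))
  expect_equal(nrow(prov), 4)  # 1 + 2 + 1 removals
})

test_that("curation is idempotent and never increases record count", {
  df <- fakeRecords(40, seed = 5)
  # engineer some duplicates and contradictions
  df$api_name[1:6] <- "dup"; df$coformer_name[1:6] <- "dup2"
  df$label[1:6] <- 1L
  df$api_name[7:8] <- "con"; df$coformer_name[7:8] <- "con2"
  df$label[7:8] <- c(0L, 1L)
  c1 <- curateDataset(df)
  expect_lte(nrow(records(c1)), nrow(df))
  c2 <- curateDataset(records(c1))
  expect_identical(records(c2), records(c1))
  expect_equal(nrow(provenance(c2)), 0)
})

test_that("empty input curates to empty output with an empty log", {
  cur <- curateDataset(fakeRecords(2)[0, ])
  expect_equal(nrow(records(cur)), 0)
  expect_equal(nrow(provenance(cur)), 0)
})

test_that("the split is a stratified partition with exact arithmetic", {
  df <- fakeRecords(244, seed = 11)
  sp <- splitTrainTest(df, testFraction = 1 / 12, seed = 3)
  expect_equal(nrow(sp$test), 19)
  expect_equal(nrow(sp$train), 225)
  # partition: disjoint and exhaustive
  key <- function(d) paste(d$api_name, d$coformer_name)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_setequal(c(key(sp$train), key(sp$test)), key(df))
  # stratification within the default tolerance
  expect_lt(abs(mean(sp$test$label) - mean(df$label)), 0.10 + 1e-9)

  # tiny corpus: the arithmetic still holds (a 2-row test part cannot
  # match four class proportions tightly, hence the looser tolerance)
  df24 <- fakeRecords(24, seed = 2)
  sp24 <- splitTrainTest(df24, 1 / 12, seed = 9, tolerance = 0.35)
  expect_equal(nrow(sp24$test), 2)
  expect_equal(nrow(sp24$train), 22)
})

test_that("the split is deterministic and validates its inputs", {
  df <- fakeRecords(60, seed = 4)
  s1 <- splitTrainTest(df, seed = 13)
  s2 <- splitTrainTest(df, seed = 13)
  expect_identical(s1, s2)
  one <- fakeRecords(20); one$label <- 1L
  expect_error(splitTrainTest(one, seed = 1), "both labels")
  expect_error(splitTrainTest(df, seed = 1, tolerance = 0,
                              maxAttempts = 5L), "tolerance")
})
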