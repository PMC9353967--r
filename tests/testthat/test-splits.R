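denseDta <- function(nDrugs, nProts, seed = 1) {
  w <- generateWorld(syntheticWorldConfig(nChemicals = nDrugs,
                                          nProteins = nProts, seed = seed))
  sampleDtaPairs(w, nDrugs * nProts, seed = seed)
}

test_that("cold splits partition entities and records follow them", {
  d <- denseDta(5, 4)
  m <- coldSplit(d, "cold_drug", c(0.6, 0.2, 0.2), seed = 2)
  expect_equal(lengths(m@entities), c(train = 3L, valid = 1L, test = 1L))
  a <- auditSplit(m, d)
  expect_true(a$ok)
  expect_true(a$coldDisjoint)
  # every record of a valid/test drug is outside train
  pr <- pairRecords(d)
  expect_length(intersect(unique(pr$left[m@train]),
                          unique(pr$left[c(m@valid, m@test)])), 0)
})

test_that("warm splits cover test entities in training on dense data", {
  d <- denseDta(6, 5)
  m <- coldSplit(d, "warm", seed = 3)
  a <- auditSplit(m, d)
  expect_true(a$ok)
  expect_true(a$warmCovered)
})

test_that("splitting is seed-deterministic and seed-sensitive", {
  d <- denseDta(8, 4)
  m1 <- coldSplit(d, "cold_drug", seed = 5)
  m2 <- coldSplit(d, "cold_drug", seed = 5)
  expect_identical(splitIndices(m1), splitIndices(m2))
  expect_identical(m1@entities, m2@entities)
  others <- vapply(1:6, function(s)
    !identical(m1@entities$train, coldSplit(d, "cold_drug", seed = 5 + s)@entities$train),
    TRUE)
  expect_true(any(others))
})

test_that("degenerate datasets are rejected with counts", {
  w <- generateWorld(syntheticWorldConfig(nChemicals = 2, nProteins = 4,
                                          seed = 6))
  d <- sampleDtaPairs(w, 8, seed = 6)
  expect_error(coldSplit(d, "cold_drug", seed = 1), ">= 3 distinct entities")
  expect_error(coldSplit(d, "cold_target",
                         fractions = c(1, 1, 1), seed = 1), "summing to 1")
})

test_that("audits hold across random datasets and all regimes", {
  for (k in 1:6) {
    d <- denseDta(sample(4:9, 1), sample(3:7, 1), seed = 40 + k)
    for (regime in c("cold_drug", "cold_target", "warm")) {
      m <- coldSplit(d, regime, seed = k)
      expect_true(auditSplit(m, d)$ok,
                  label = paste(regime, "seed", k))
    }
  }
})

test_that("the leakage detector catches corrupted manifests", {
  d <- denseDta(6, 4)
  m <- coldSplit(d, "cold_drug", seed = 9)
  bad <- m
  bad@test <- c(bad@test, bad@train[1])
  bad@train <- bad@train[-1]
  expect_false(auditSplit(bad, d)$coldDisjoint)
})

test_that("manifests round-trip through JSON", {
  d <- denseDta(6, 4)
  m <- coldSplit(d, "cold_target", seed = 12)
  path <- tempfile(fileext = ".json")
  writeSplitManifest(m, path)
  back <- readSplitManifest(path)
  expect_identical(splitIndices(back), splitIndices(m))
  expect_identical(back@regime, m@regime)
  expect_equal(back@fractions, m@fractions)
  expect_identical(back@entities, m@entities)
})
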