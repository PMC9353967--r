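test_that("metrics reproduce their closed-form values", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pearsonR(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(spearmanRho(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(1, 1), c(0, 0)), 1)
  expect_equal(spearmanRho(c(1, 3, 2), c(1, 2, 3)), 0.5)
})

test_that("concordance index follows the tie-aware pairwise definition", {
  expect_equal(concordanceIndex(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(concordanceIndex(c(3, 2, 1), c(1, 2, 3)), 0)
  expect_equal(concordanceIndex(c(1, 3, 2), c(1, 2, 3)), 2 / 3)
  # predicted tie gets half credit
  expect_equal(concordanceIndex(c(1, 1), c(0, 2)), 0.5)
  # pairs with tied labels are excluded entirely
  expect_equal(concordanceIndex(c(5, 1, 2), c(1, 1, 2)), 0.5)
})

test_that("concordance index matches independent oracles on random ties", {
  set.seed(42)
  for (rep in seq_len(50)) {
    n <- sample(3:50, 1)
    lab <- sample(1:6, n, replace = TRUE)   # heavy label ties
    pred <- sample(1:8, n, replace = TRUE)  # heavy prediction ties
    if (length(unique(lab)) < 2) next
    ours <- concordanceIndex(pred, lab)
    expect_equal(ours, bruteForceCI(pred, lab))
    # cross-check against survival's concordance on a subset of cases
    if (rep %% 10 == 0) {
      sc <- survival::concordance(lab ~ pred)$concordance
      expect_equal(ours, sc, tolerance = 1e-12)
    }
  }
})

test_that("undefined metrics signal instead of returning silent numbers", {
  expect_warning(p <- pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_true(is.na(p))
  expect_warning(s <- spearmanRho(c(2, 2), c(1, 3)), "zero-variance")
  expect_true(is.na(s))
  expect_warning(ci <- concordanceIndex(c(1, 2), c(5, 5)), "tied")
  expect_true(is.na(ci))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("metric ranges hold on random inputs", {
  set.seed(7)
  for (i in seq_len(20)) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_gte(rmse(a, b), 0)
    expect_true(abs(pearsonR(a, b)) <= 1)
    expect_true(abs(spearmanRho(a, b)) <= 1)
    ci <- concordanceIndex(a, b)
    expect_true(ci >= 0 && ci <= 1)
  }
})
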