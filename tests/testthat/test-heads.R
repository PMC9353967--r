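test_that("joinPair concatenates in fixed order", {
  expect_equal(joinPair(c(1, 2), c(3, 4)), c(1, 2, 3, 4))
  expect_length(joinPair(rnorm(128), rnorm(128)), 256)
  a <- c(1, 2); b <- c(2, 1)
  expect_false(identical(joinPair(a, b), joinPair(b, a)))
  expect_error(joinPair(1:3, 1:2), "lengths differ")
})

test_that("classification head is a bounded probability", {
  cfg <- pairHeadConfig(inputDim = 3L, hidden = 4L, task = "cci")
  zero <- list("H.W" = matrix(0, 6, 4), "H.b" = numeric(4),
               "O.W" = matrix(0, 4, 1), "O.b" = 0)
  expect_equal(classifyInteraction(rnorm(6), zero, cfg), 0.5)
  params <- initHeadParams(cfg, seed = 4)
  set.seed(8)
  for (i in 1:10) {
    p <- classifyInteraction(rnorm(6, sd = 5), params, cfg)
    expect_true(p > 0 && p < 1)
  }
  x <- rnorm(6)
  expect_identical(classifyInteraction(x, params, cfg),
                   classifyInteraction(x, params, cfg))
})

test_that("literal single-layer head reproduces sigmoid(relu(Wx+b))", {
  cfg <- pairHeadConfig(inputDim = 2L, task = "cci", literal = TRUE)
  params <- list("O.W" = matrix(c(1, -1, 0.5, 2), 4, 1), "O.b" = -0.2)
  x <- c(0.3, -0.1, 0.7, 0.2)
  expect_equal(classifyInteraction(x, params, cfg),
               1 / (1 + exp(-max(0, sum(x * params$`O.W`) - 0.2))))
  # the literal form cannot express probabilities below 0.5
  expect_gte(classifyInteraction(c(-9, -9, -9, -9), params, cfg), 0.5)
})

test_that("regression head matches a brute-force forward pass", {
  cfg <- pairHeadConfig(inputDim = 2L, hidden = 3L, task = "dta")
  params <- initHeadParams(cfg, seed = 11)
  x <- rep(1, 4)
  manual <- drop(pmax(x %*% params$`H.W` + params$`H.b`, 0) %*%
                   params$`O.W` + params$`O.b`)
  expect_equal(predictAffinity(x, params, cfg), manual)
  # constant head: zero weights, output bias c
  zero <- list("H.W" = matrix(0, 4, 3), "H.b" = numeric(3),
               "O.W" = matrix(0, 3, 1), "O.b" = 2.5)
  expect_equal(predictAffinity(rnorm(4), zero, cfg), 2.5)
})

test_that("regression head is affine when the inner activation is off", {
  cfg <- pairHeadConfig(inputDim = 2L, hidden = 3L, task = "dta",
                        activation = "none")
  params <- initHeadParams(cfg, seed = 5)
  x <- rnorm(4)
  f <- function(z) predictAffinity(z, params, cfg)
  expect_equal(f(2.5 * x) - f(0 * x), 2.5 * (f(x) - f(0 * x)))
})

test_that("task losses follow their definitions", {
  expect_equal(taskLoss(c(0, 0), c(1, 1), "dta"), 1)
  expect_equal(taskLoss(c(1, 2), c(1, 2), "dta"), 0)
  expect_equal(taskLoss(c(0.5, 0.5), c(0, 1), "cci"), log(2))
  p <- c(1 - 1e-9, 1e-9)
  expect_lt(taskLoss(p, c(1, 0), "ppi"), 1e-6)
  expect_error(taskLoss(numeric(0), numeric(0), "dta"), "empty batch")
  expect_error(taskLoss(c(0.3), c(0.5), "cci"), "0/1")
  set.seed(2)
  expect_gte(taskLoss(rnorm(10), rnorm(10), "dta"), 0)
})
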