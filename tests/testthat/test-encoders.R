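test_that("ginLayer implements epsilon-weighted sum aggregation", {
  # two connected nodes, identity MLP: each receives self + neighbour
  X <- matrix(c(1, 1), 2, 1)
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(ginLayer(X, A, 0, identity), matrix(c(2, 2), 2, 1))
  # isolated node passes through
  expect_equal(ginLayer(matrix(5, 1, 1), matrix(0, 1, 1), 0, identity),
               matrix(5, 1, 1))
  # 3-cycle, eps = 0.5: node 1 gets 1.5*1 + (2 + 3)
  X3 <- matrix(c(1, 2, 3), 3, 1)
  A3 <- matrix(1, 3, 3) - diag(3)
  out <- ginLayer(X3, A3, 0.5, identity)
  expect_equal(out[1, 1], 6.5)
})

test_that("ginLayer equals (1+eps)X + AX under the identity map", {
  set.seed(5)
  for (i in seq_len(25)) {
    n <- sample(2:12, 1)
    A <- matrix(rbinom(n * n, 1, 0.4), n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    X <- matrix(rnorm(n * 3), n, 3)
    eps <- runif(1, -0.5, 1)
    expect_equal(ginLayer(X, A, eps, identity), (1 + eps) * X + A %*% X)
  }
})

test_that("dimension mismatches against the layer MLP are contract errors", {
  mlp <- list(W1 = matrix(1, 4, 2), b1 = numeric(2),
              W2 = matrix(1, 2, 2), b2 = numeric(2))
  expect_error(ginLayer(matrix(1, 2, 3), matrix(0, 2, 2), 0, mlp),
               "expects 4 input features")
})

test_that("graph encoding is permutation invariant and fixed-length", {
  state <- initEncoderState(smallGinConfig, seed = 3)
  set.seed(21)
  for (g in tinyGraphs) {
    x <- encodeGraph(g, state)
    expect_length(x, smallGinConfig$outputDim)
    perm <- sample(nrow(nodeFeatures(g)))
    xp <- encodeGraph(permuteGraph(g, perm), state)
    expect_equal(x, xp, tolerance = 1e-6)
  }
})

test_that("max pooling picks coordinate-wise maxima", {
  H <- matrix(c(1, 3, 4, 2), 2, 2) # rows: nodes; expect max [3, 4]
  pool <- AffinityTransfer:::poolMaxForward(H, list(1:2))
  expect_equal(drop(pool$P), c(3, 4))
  # single-node graph: pooled vector is that node's vector
  pool1 <- AffinityTransfer:::poolMaxForward(H, list(1L, 2L))
  expect_equal(pool1$P, H)
})

test_that("sequence encoding means token embeddings then projects", {
  cfg <- sequenceEncoderConfig(vocab = c("A", "B", "X"), embeddingDim = 2L,
                               outputDim = 1L)
  state <- initEncoderState(cfg, seed = 1)
  state@params$E <- rbind(c(1, 0), c(0, 1), c(0, 0))
  state@params$`P.W` <- matrix(c(1, 0), 2, 1) # picks the first coordinate
  state@params$`P.b` <- 0
  expect_equal(encodeSequence("AAB", state), 2 / 3)
  # order invariance for a lookup (non-contextual) provider
  expect_equal(encodeSequence("ABA", state), encodeSequence("AAB", state))
  # length-1 sequence: projection of that token's embedding
  expect_equal(encodeSequence("B", state), 0)
  # unknown tokens map to 'X' with a warning
  expect_warning(v <- encodeSequence("AZB", state), "outside the vocabulary")
  expect_equal(v, 1 / 3)
})

test_that("external providers plug in through the token contract", {
  cfg <- sequenceEncoderConfig(providerName = "external",
                               vocab = c("A", "B", "X"), embeddingDim = 4L,
                               outputDim = 2L, providerTrainable = FALSE)
  state <- initEncoderState(cfg, seed = 2)
  E <- matrix(seq_len(12) / 10, 3, 4)
  prov <- matrixProvider(E)
  v1 <- encodeSequence("ABAB", state, provider = prov)
  expect_length(v1, 2L)
  # deterministic given fixed parameters
  expect_identical(v1, encodeSequence("ABAB", state, provider = prov))
  # provider emitting the wrong row count violates the contract
  badProv <- function(tokens) E[1:2, , drop = FALSE]
  expect_error(encodeSequence("ABAB", state, provider = badProv),
               "one embedding row per token")
})

test_that("siamese use of one encoder is bit-identical across branches", {
  state <- initEncoderState(smallGinConfig, seed = 9)
  g <- tinyGraphs[[1]]
  expect_identical(encodeGraph(g, state), encodeGraph(g, state))
})

test_that("encoder checkpoints round-trip bit-exactly with fingerprints", {
  state <- initEncoderState(smallGinConfig, seed = 17)
  path <- tempfile(fileext = ".rds")
  saveEncoderState(state, path)
  back <- readEncoderState(path)
  expect_identical(encoderParams(back), encoderParams(state))
  expect_identical(back@fingerprint, state@fingerprint)
  # a sequence config must refuse projection wider than the embedding
  expect_error(sequenceEncoderConfig(embeddingDim = 8, outputDim = 8),
               "smaller than embeddingDim")
})
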