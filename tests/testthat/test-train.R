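test_that("zero-epoch pretraining returns the untouched initialization", {
  res <- pretrainEncoder(tinyCci, smallGinConfig, fastTrain(epochs = 0),
                         graphs = tinyGraphs)
  init <- initEncoderState(smallGinConfig, seed = 1)
  expect_identical(encoderParams(res$state), encoderParams(init))
})

test_that("pretraining is deterministic under a fixed seed", {
  r1 <- pretrainEncoder(tinyCci, smallGinConfig, fastTrain(epochs = 2),
                        graphs = tinyGraphs)
  r2 <- pretrainEncoder(tinyCci, smallGinConfig, fastTrain(epochs = 2),
                        graphs = tinyGraphs)
  expect_identical(encoderParams(r1$state), encoderParams(r2$state))
  expect_identical(r1$log, r2$log)
})

test_that("a single optimization step trains the encoder through the head", {
  cci2 <- tinyCci
  cci2@pairs <- cci2@pairs[1:2, ]
  res <- pretrainEncoder(cci2, smallGinConfig,
                         fastTrain(epochs = 1, seed = 6), graphs = tinyGraphs,
                         standardize = FALSE)
  init <- initEncoderState(smallGinConfig, seed = 6)
  moved <- vapply(names(encoderParams(init)), function(nm)
    any(encoderParams(res$state)[[nm]] != encoderParams(init)[[nm]]), TRUE)
  expect_true(any(moved))
})

test_that("pretraining rejects datasets of the wrong entity type", {
  expect_error(pretrainEncoder(tinyPpi, smallGinConfig, fastTrain()),
               "cannot pretrain on PPI")
  expect_error(pretrainEncoder(tinyDta, smallGinConfig, fastTrain()),
               "CCI or PPI")
})

test_that("assembly transfers checkpoints and verifies fingerprints", {
  pt <- pretrainEncoder(tinyCci, smallGinConfig, fastTrain(epochs = 2),
                        graphs = tinyGraphs)
  # round-trip the checkpoint through disk first: transfer fidelity
  path <- tempfile(fileext = ".rds")
  saveEncoderState(pt$state, path)
  st <- readEncoderState(path)
  expect_identical(encoderParams(st), encoderParams(pt$state))

  model <- assembleDtaModel(smallGinConfig, smallSeqConfig, drugState = st,
                            seed = 5)
  expect_identical(model@drugEncoder@params, encoderParams(pt$state))
  expect_identical(model@info$drugOrigin, "pretrained")
  expect_identical(model@info$proteinOrigin, "fresh")

  fresh <- assembleDtaModel(smallGinConfig, smallSeqConfig, seed = 5)
  expect_identical(fresh@drugEncoder@params,
                   encoderParams(initEncoderState(smallGinConfig,
                                                  deriveSeed(5L, 41L))))

  other <- ginEncoderConfig(hiddenDim = 6L, readoutHidden = 6L,
                            outputDim = 4L, numLayers = 3L)
  expect_error(assembleDtaModel(other, smallSeqConfig, drugState = st),
               "numLayers")
})

test_that("frozen transfer leaves encoder parameters untouched", {
  pt <- pretrainEncoder(tinyCci, smallGinConfig, fastTrain(epochs = 2),
                        graphs = tinyGraphs)
  split <- coldSplit(tinyDta, "warm", seed = 2)
  base <- assembleDtaModel(smallGinConfig, smallSeqConfig,
                           drugState = pt$state, seed = 3)
  frozen <- trainDta(base, split, tinyDta,
                     fastTrain(epochs = 2, encoderMode = "transfer_frozen"),
                     graphs = tinyGraphs)
  expect_identical(frozen$model@drugEncoder@params, encoderParams(pt$state))
  tuned <- trainDta(base, split, tinyDta,
                    fastTrain(epochs = 2, encoderMode = "transfer_finetune"),
                    graphs = tinyGraphs)
  expect_false(identical(tuned$model@drugEncoder@params,
                         encoderParams(pt$state)))
  # head trains in both modes
  expect_false(identical(frozen$model@head, base@head))
})

test_that("a constant-affinity world collapses to the constant predictor", {
  cfg <- syntheticWorldConfig(nChemicals = 12, nProteins = 8,
                              affinityScale = 0, affinityNoiseSd = 0,
                              affinityIntercept = 4.2, seed = 19)
  w <- generateWorld(cfg)
  d <- sampleDtaPairs(w, 90, seed = 2)
  split <- coldSplit(d, "warm", seed = 3)
  model <- assembleDtaModel(smallGinConfig, smallSeqConfig, seed = 4)
  res <- trainDta(model, split, d,
                  trainConfig(epochs = 300, seed = 4, batchSize = Inf,
                              learningRate = 0.01))
  testRmse <- res$metrics$value[res$metrics$split == "test" &
                                  res$metrics$metric == "rmse"]
  expect_lt(testRmse, 0.1) # test labels have zero spread; predictor matches
})

test_that("replicate-seed reporting aggregates runs", {
  split <- coldSplit(tinyDta, "warm", seed = 7)
  model <- assembleDtaModel(smallGinConfig, smallSeqConfig, seed = 1)
  res <- trainDta(model, split, tinyDta, fastTrain(epochs = 2),
                  graphs = tinyGraphs, replicateSeeds = c(1, 2, 3))
  expect_equal(sort(unique(res$metrics$run)), 1:3)
  expect_setequal(res$summary$metric, c("rmse", "pearson", "spearman", "ci"))
  expect_true(all(is.finite(res$summary$sd)))
  expect_length(res$runs, 3)
})

test_that("training logs expose per-epoch losses for both phases", {
  pt <- pretrainEncoder(tinyPpi, smallSeqConfig, fastTrain(epochs = 3))
  expect_setequal(unique(pt$log$split), c("train", "valid"))
  expect_equal(max(pt$log$epoch), 3)
  expect_true(all(is.finite(pt$log$loss)))
})
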