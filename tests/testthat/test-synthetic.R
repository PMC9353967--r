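test_that("worlds are deterministic in their seed and structurally valid", {
  cfg <- syntheticWorldConfig(nChemicals = 25, nProteins = 15, seed = 8)
  w1 <- generateWorld(cfg)
  w2 <- generateWorld(cfg)
  expect_identical(worldChemicals(w1), worldChemicals(w2))
  expect_identical(worldProteins(w1), worldProteins(w2))
  expect_identical(worldLatents(w1), worldLatents(w2))

  big <- generateWorld(syntheticWorldConfig(nChemicals = 100, nProteins = 5,
                                            seed = 9))
  expect_equal(length(unique(worldChemicals(big)$id)), 100)
  parsed <- suppressWarnings(parseSmilesSet(
    setNames(worldChemicals(big)$smiles, worldChemicals(big)$id)))
  expect_length(parsed$failed, 0)
  # proteins use the 20 standard residues only
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]",
                         worldProteins(big)$sequence)))
})

test_that("latents are deterministic functions of observable structure", {
  w <- tinyWorld
  uHat <- (w@fragCounts / sqrt(rowSums(w@fragCounts^2))) %*%
    w@loadings$fragment
  expect_equal(unname(uHat), unname(worldLatents(w)), tolerance = 1e-12)
  vHat <- (w@motifCounts / sqrt(rowSums(w@motifCounts^2))) %*%
    w@loadings$motif
  expect_equal(unname(vHat), unname(worldLatents(w, "protein")),
               tolerance = 1e-12)
  # motif placements are visible in the sequences themselves
  hits <- vapply(seq_len(nrow(w@motifCounts)), function(j) {
    s <- worldProteins(w)$sequence[j]
    sum(vapply(colnames(w@motifCounts), function(mf)
      length(gregexpr(mf, s, fixed = TRUE)[[1]][
        gregexpr(mf, s, fixed = TRUE)[[1]] > 0]), 1L))
  }, 1L)
  expect_true(all(hits >= rowSums(w@motifCounts)))
})

test_that("interaction sampling follows the logistic latent model", {
  w <- tinyWorld
  # steep link, no label noise: labels are a threshold on the latent dot
  cfgSteep <- syntheticWorldConfig(nChemicals = 15, nProteins = 10,
                                   beta = 500, bias = 0, labelNoise = 0,
                                   seed = 11)
  ws <- generateWorld(cfgSteep)
  d <- sampleInteractionPairs(ws, "cci", 60, seed = 3)
  pr <- pairRecords(d)
  dots <- rowSums(worldLatents(ws)[match(pr$left, worldChemicals(ws)$id), ] *
                    worldLatents(ws)[match(pr$right, worldChemicals(ws)$id), ])
  clear <- abs(dots) > 0.05
  expect_true(all(pr$label[clear] == as.integer(dots[clear] > 0)))

  # classes are balanced by construction
  expect_equal(sum(pr$label), 30)

  # unsatisfiable balance requests fail with the achieved ratio
  cfgNeg <- syntheticWorldConfig(nChemicals = 10, nProteins = 5, beta = 0,
                                 bias = -30, labelNoise = 0, seed = 12)
  wn <- generateWorld(cfgNeg)
  expect_error(sampleInteractionPairs(wn, "cci", 40, seed = 1),
               "could not balance")
})

test_that("a latent oracle separates default interaction pairs", {
  # noise-free link first: the oracle ranking is near-perfect
  wc <- generateWorld(syntheticWorldConfig(nChemicals = 80, nProteins = 40,
                                           labelNoise = 0, seed = 13))
  dc <- sampleInteractionPairs(wc, "cci", 2000, seed = 5)
  prc <- pairRecords(dc)
  Uc <- worldLatents(wc)
  scoreC <- rowSums(Uc[match(prc$left, worldChemicals(wc)$id), ] *
                      Uc[match(prc$right, worldChemicals(wc)$id), ])
  expect_gt(concordanceIndex(scoreC, prc$label), 0.95)

  # with the default 5% label flips even a perfect ranker is capped near
  # (1 - eta)^2 + eta(1 - eta); the oracle must stay close to that ceiling
  w <- generateWorld(syntheticWorldConfig(nChemicals = 80, nProteins = 40,
                                          seed = 13))
  d <- sampleInteractionPairs(w, "cci", 2000, seed = 5)
  pr <- pairRecords(d)
  U <- worldLatents(w)
  score <- rowSums(U[match(pr$left, worldChemicals(w)$id), ] *
                     U[match(pr$right, worldChemicals(w)$id), ])
  expect_gt(concordanceIndex(score, pr$label), 0.9)
})

test_that("affinities are bilinear in the latents plus noise", {
  cfg0 <- syntheticWorldConfig(nChemicals = 30, nProteins = 20,
                               affinityNoiseSd = 0, seed = 14)
  w0 <- generateWorld(cfg0)
  d0 <- sampleDtaPairs(w0, 200, seed = 2)
  pr <- pairRecords(d0)
  dots <- rowSums(worldLatents(w0)[match(pr$left, worldChemicals(w0)$id), ] *
                    worldLatents(w0, "protein")[match(pr$right, worldProteins(w0)$id), ])
  expect_equal(pr$label, unname(cfg0$affinityScale * dots +
                                  cfg0$affinityIntercept),
               tolerance = 1e-12)

  # with noise, the latent oracle's residual is the injected sigma
  w <- generateWorld(syntheticWorldConfig(nChemicals = 100, nProteins = 60,
                                          seed = 15))
  d <- sampleDtaPairs(w, 3000, seed = 3)
  pr <- pairRecords(d)
  dots <- rowSums(worldLatents(w)[match(pr$left, worldChemicals(w)$id), ] *
                    worldLatents(w, "protein")[match(pr$right, worldProteins(w)$id), ])
  fit <- lm(pr$label ~ dots)
  expect_equal(sqrt(mean(residuals(fit)^2)), 0.3, tolerance = 0.1)
})

test_that("structure counts identify the affinity surface", {
  w <- generateWorld(syntheticWorldConfig(affinityNoiseSd = 0.1, seed = 16))
  d <- sampleDtaPairs(w, 3000, seed = 4)
  pr <- pairRecords(d)
  F <- w@fragCounts / sqrt(rowSums(w@fragCounts^2))
  M <- w@motifCounts / sqrt(rowSums(w@motifCounts^2))
  fi <- match(pr$left, rownames(F))
  gj <- match(pr$right, rownames(M))
  X <- t(vapply(seq_len(nrow(pr)), function(r) as.vector(outer(F[fi[r], ], M[gj[r], ])),
                numeric(ncol(F) * ncol(M))))
  fit <- lm(pr$label ~ X)
  r2 <- summary(fit)$r.squared
  expect_gt(r2, 0.8)
})

test_that("evidence channels filter only the CCI record set", {
  d <- tinyCci
  f <- filterEvidence(d, "experimental")
  expect_true(all(pairRecords(f)$channel == "experimental"))
  expect_identical(entityStore(f), entityStore(d))
  expect_error(filterEvidence(tinyDta), "only exist for CCI")
  expect_error(filterEvidence(d, "no-such-channel"), "no records left")
})

test_that("emitted entities round-trip through graphs and tokenizer", {
  expect_length(tinyGraphs, nrow(worldChemicals(tinyWorld)))
  for (s in worldProteins(tinyWorld)$sequence[1:3]) {
    expect_silent(toks <- tokenizeSequence(s))
    expect_length(toks, nchar(s))
  }
})
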