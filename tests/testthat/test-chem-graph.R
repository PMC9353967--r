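test_that("atom featurization lays out the fixed one-hot blocks", {
  cfg <- atomFeatureConfig()
  nEl <- length(cfg$elementVocab)
  f <- featurizeAtom(list(element = "C", degree = 0, numH = 4,
                          implicitValence = 4, aromatic = FALSE), cfg)
  expect_length(f, cfg$featureLength)
  expect_equal(which(f == 1),
               c(match("C", cfg$elementVocab),       # element block
                 nEl + 1,                            # degree slot 0
                 nEl + cfg$maxDegree + 5,            # numH slot 4
                 nEl + cfg$maxDegree + cfg$maxNumH + 5)) # valence slot 4
  # each one-hot block contributes exactly one 1; aromatic bit separate
  expect_equal(sum(f), 4)
})

test_that("unknown elements and oversized descriptors are absorbed", {
  cfg <- atomFeatureConfig()
  expect_warning(
    f <- featurizeAtom(list(element = "Xx", degree = 0, numH = 0,
                            implicitValence = 0, aromatic = FALSE), cfg),
    "Unknown")
  expect_equal(sum(f), 4)
  expect_equal(f[match("Unknown", cfg$elementVocab)], 1)
  # clipping into the last slot instead of erroring
  g <- featurizeAtom(list(element = "C", degree = 99, numH = 99,
                          implicitValence = 99, aromatic = TRUE), cfg)
  nEl <- length(cfg$elementVocab)
  expect_equal(g[nEl + cfg$maxDegree], 1)
  expect_equal(g[cfg$featureLength], 1)
  # determinism
  d <- list(element = "N", degree = 2, numH = 1, implicitValence = 1,
            aromatic = TRUE)
  expect_identical(featurizeAtom(d, cfg), featurizeAtom(d, cfg))
})

test_that("small molecules yield the expected graphs", {
  g2 <- smilesToGraph("CC")
  expect_equal(adjacency(g2), matrix(c(0, 1, 1, 0), 2))
  expect_equal(g2@atoms$numH, c(3, 3))

  g3 <- smilesToGraph("C1CC1")
  expect_equal(nrow(adjacency(g3)), 3)
  expect_equal(rowSums(adjacency(g3)), rep(2, 3))

  gb <- smilesToGraph("c1ccccc1")
  expect_equal(nrow(adjacency(gb)), 6)
  expect_equal(sum(adjacency(gb)) / 2, 6) # 6 ring bonds
  expect_true(all(gb@atoms$aromatic))
  expect_equal(gb@atoms$degree, rep(2, 6))
  expect_equal(gb@atoms$numH, rep(1, 6))

  g1 <- smilesToGraph("C") # methane: one heavy atom, no bonds
  expect_equal(nrow(adjacency(g1)), 1)
  expect_equal(g1@atoms$numH, 4)
  expect_equal(g1@atoms$implicitValence, 4)
})

test_that("parse errors are explicit and name the offender", {
  expect_error(smilesToGraph("NOT((A_SMILES"), "NOT\\(\\(A_SMILES")
  expect_error(smilesToGraph(""), "non-empty")
  res <- suppressWarnings(parseSmilesSet(c(a = "CCO", b = "BAD((", c = "CC")))
  expect_setequal(names(res$graphs), c("a", "c"))
  expect_equal(res$failed, "b")
})

test_that("graph invariants hold across generated molecules", {
  cfg <- atomFeatureConfig()
  nEl <- length(cfg$elementVocab)
  blocks <- list(seq_len(nEl),
                 nEl + seq_len(cfg$maxDegree),
                 nEl + cfg$maxDegree + seq_len(cfg$maxNumH),
                 nEl + cfg$maxDegree + cfg$maxNumH +
                   seq_len(cfg$maxImplicitValence))
  for (g in tinyGraphs) {
    A <- adjacency(g)
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0))
    X <- nodeFeatures(g)
    for (b in blocks) expect_equal(unname(rowSums(X[, b, drop = FALSE])),
                                   rep(1, nrow(X)))
  }
})

test_that("edge counts agree with an independent SMILES parser", {
  set.seed(99)
  worlds <- generateWorld(syntheticWorldConfig(nChemicals = 100L,
                                               nProteins = 2L, seed = 31L))
  smiles <- worldChemicals(worlds)$smiles
  graphs <- suppressWarnings(parseSmilesSet(setNames(smiles, paste0("m", seq_along(smiles)))))$graphs
  ours <- vapply(graphs, function(g) sum(adjacency(g)) / 2, 1)
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "for line in sys.stdin:",
    "    m = Chem.MolFromSmiles(line.strip())",
    "    print(m.GetNumBonds())", sep = "\n")
  out <- system2("python", c("-c", shQuote(script)),
                 input = smiles, stdout = TRUE)
  expect_equal(unname(ours), as.numeric(out))
})

test_that("graph caches round-trip with a config guard", {
  path <- tempfile(fileext = ".rds")
  writeGraphCache(tinyGraphs, path)
  back <- readGraphCache(path)
  expect_identical(lapply(back, nodeFeatures), lapply(tinyGraphs, nodeFeatures))
  other <- atomFeatureConfig(maxDegree = 6)
  expect_error(readGraphCache(path, other), "different feature configuration")
})
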