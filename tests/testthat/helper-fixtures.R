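# Shared small fixtures, built in code at load time. Kept deliberately tiny:
# a 15-chemical / 10-protein world is enough to exercise every code path.

tinyWorld <- generateWorld(syntheticWorldConfig(nChemicals = 15L,
                                                nProteins = 10L, seed = 11L))
tinyGraphs <- suppressWarnings(parseSmilesSet(
  setNames(worldChemicals(tinyWorld)$smiles, worldChemicals(tinyWorld)$id)))$graphs

tinyCci <- sampleInteractionPairs(tinyWorld, "cci", 80, seed = 12L)
tinyPpi <- sampleInteractionPairs(tinyWorld, "ppi", 80, seed = 13L)
tinyDta <- sampleDtaPairs(tinyWorld, 120, seed = 14L)

smallGinConfig <- ginEncoderConfig(hiddenDim = 6L, readoutHidden = 6L,
                                   outputDim = 4L)
smallSeqConfig <- sequenceEncoderConfig(embeddingDim = 8L, outputDim = 4L)
fastTrain <- function(epochs = 3L, seed = 1L, ...)
  trainConfig(epochs = epochs, seed = seed, batchSize = Inf,
              learningRate = 0.003, ...)

# apply a node permutation to a molecule graph
permuteGraph <- function(g, perm) {
  methods::new("MoleculeGraph",
               nodeFeatures = nodeFeatures(g)[perm, , drop = FALSE],
               adjacency = adjacency(g)[perm, perm, drop = FALSE],
               atoms = g@atoms[perm, , drop = FALSE],
               smiles = g@smiles)
}

# O(n^2) reference concordance index, written independently of the package
# implementation (explicit double loop).
bruteForceCI <- function(pred, lab) {
  num <- 0; den <- 0
  n <- length(lab)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (lab[i] > lab[j]) {
      den <- den + 1
      if (pred[i] > pred[j]) num <- num + 1
      else if (pred[i] == pred[j]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}
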