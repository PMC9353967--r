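# AffinityTransfer

Transfer learning for drug-target affinity (DTA) prediction with
cold-start evaluation, in R.

## The problem

Predicting the real-valued binding affinity between a small molecule and a
protein is hardest exactly where it is most useful: for *new* drugs and
*new* targets that never appear in the training data (the cold-drug and
cold-target settings). Affinity labels are scarce, but pairwise
*interaction* labels are abundant: chemical-chemical interaction (CCI)
corpora and protein-protein interaction (PPI) networks cover orders of
magnitude more entities. This package implements the transfer strategy
that exploits that asymmetry:

1. **Pretrain** a drug encoder on CCI pairs and a protein encoder on PPI
   pairs, each as a siamese classifier: one shared encoder embeds both
   pair members, the concatenated embeddings pass through a small head,
   and binary cross-entropy is minimized.
2. **Transfer** the pretrained encoders into the affinity model and train
   the regressor with mean squared error under Adam, selecting the epoch
   by validation loss.

The drug encoder is a graph isomorphism network (GIN) over heavy-atom
molecular graphs built from SMILES: node features are fixed one-hot blocks
(43 element symbols, 10 slots each for degree / hydrogen count / implicit
valence, one aromatic bit; 74 features), and each of the k = 5 layers
updates

    p_v  <-  MLP( (1 + eps) * p_v + sum_{u in N(v)} p_u ),

followed by coordinate-wise max pooling and a two-layer affine readout.
The protein encoder maps a residue sequence through a token-embedding
provider (any protein language model via a plug-in contract; a trainable
lookup table at desk scale) to an n x d matrix, averages over tokens, and
projects d = 768 to d' = 128 with one affine layer. Heads join the two
branch vectors by plain concatenation.

Evaluation uses the four standard regression benchmarks — RMSE, Pearson,
Spearman, and the concordance index (CI; half credit for predicted ties,
tied-label pairs excluded) — under entity-disjoint cold splits whose
hygiene is independently auditable.

## A worked example

Everything below runs offline on a synthetic world in which chemicals,
proteins and all three tasks share one latent structure — so transfer is
beneficial by construction and the whole pipeline is testable at desk
scale:

```r
library(AffinityTransfer)

world <- generateWorld(syntheticWorldConfig(nChemicals = 80,
                                            nProteins = 50, seed = 7))
cci <- sampleInteractionPairs(world, "cci", 600, seed = 1)
dta <- sampleDtaPairs(world, 900, seed = 2)

drugCfg <- ginEncoderConfig(hiddenDim = 12, readoutHidden = 12,
                            outputDim = 8)
protCfg <- sequenceEncoderConfig(embeddingDim = 16, outputDim = 8)

pre <- pretrainEncoder(cci, drugCfg,
                       trainConfig(epochs = 300, batchSize = Inf,
                                   learningRate = 0.005, seed = 3,
                                   headHidden = 64))
tail(subset(pre$log, split == "valid"), 1)
#>     epoch split      loss       auc
#> 600   300 valid 0.4357179 0.8933333

split <- coldSplit(dta, "cold_drug", seed = 4)
model <- assembleDtaModel(drugCfg, protCfg, drugState = pre$state, seed = 5)
fit <- trainDta(model, split, dta,
                trainConfig(epochs = 300, batchSize = Inf,
                            learningRate = 0.005, seed = 6))
subset(fit$metrics, split == "test")
#>   run split   metric     value
#> 5   1  test     rmse 2.7568680
#> 6   1  test  pearson 0.5633371
#> 7   1  test spearman 0.5721153
#> 8   1  test       ci 0.7039925
```

The pretraining log's `auc` column is the concordance of the classifier
score with the held-out 0/1 interaction labels (equal to ROC AUC). In the
affinity report, `rmse` is on the affinity scale of the generator (a
pKd-like scale centered near 6 with unit-to-few spread); `ci` is the
probability that a randomly chosen higher-affinity pair is ranked above a
lower-affinity one — 0.5 is chance, 1.0 perfect.

The headline experiment — pretrained versus from-scratch encoders across
cold-drug / cold-target / warm regimes over replicate worlds — is a single
call:

```r
exp <- runTransferExperiment(rootSeed = 1)  # ~15 min on one CPU
exp$summary
```

A command-line surface over the same pipeline
(`simulate / split / pretrain-cci / pretrain-ppi / train-dta / evaluate`)
is available through `runCli()` and the installed
`inst/scripts/affinity-transfer` wrapper; the seeded chain is
bit-reproducible.

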