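#' Pretrained-versus-scratch transfer experiment
#'
#' The package's headline experiment: on synthetic worlds where CCI, PPI and
#' DTA share one latent structure, compare affinity models whose encoders
#' were pretrained on the auxiliary tasks against identically configured
#' from-scratch models, across evaluation regimes. For each replicate seed
#' the experiment generates a fresh world, samples the three datasets,
#' pretrains a drug encoder on CCI and a protein encoder on PPI, and trains
#' affinity models in matched arms:
#' \itemize{
#'   \item cold_drug: CCI-pretrained drug encoder vs scratch (protein
#'     encoder scratch in both);
#'   \item cold_target: PPI-pretrained protein encoder vs scratch (drug
#'     encoder scratch in both);
#'   \item warm: both pretrained arms and the scratch arm, to measure how
#'     much smaller the pretraining gap becomes when test entities were seen
#'     in training.
#' }
#'
#' @param worldConfig a [syntheticWorldConfig()]; its seed is re-derived per
#'   replicate.
#' @param nCci,nPpi,nDta dataset sizes (defaults 2000 / 2000 / 3000).
#' @param seeds integer vector of replicate seeds (default 1:10).
#' @param rootSeed integer combined with each replicate index to derive all
#'   per-replicate seeds.
#' @param encoderDim,hiddenDim,embeddingDim desk-scale encoder widths used
#'   for the experiment arms (the configuration defaults stay at the
#'   full-scale values; these smaller widths keep a 10-replicate experiment
#'   within minutes on one CPU).
#' @param pretrainEpochs,dtaEpochs,learningRate training recipe for the
#'   pretraining and affinity phases.
#' @param dtaMode how transferred encoders behave during affinity training
#'   in the pretrained arms: "transfer_finetune", "transfer_frozen", or
#'   "select" (default), which trains the pretrained arm both ways and
#'   keeps the variant with the lower validation loss — the linear-probe
#'   versus fine-tune choice made on validation, never on test.
#' @param regimes evaluation regimes to run.
#' @return A list with `results` (tidy data.frame: seed, regime, arm,
#'   metric, value) and `summary` (per-regime win counts of the pretrained
#'   arm and mean RMSE gaps).
#' @export
runTransferExperiment <- function(worldConfig = syntheticWorldConfig(),
                                  nCci = 2000L, nPpi = 2000L, nDta = 3000L,
                                  seeds = 1:10, rootSeed = 1L,
                                  encoderDim = 8L, hiddenDim = 12L,
                                  embeddingDim = 16L,
                                  pretrainEpochs = 1000L, dtaEpochs = 1500L,
                                  learningRate = 0.005,
                                  dtaMode = "select",
                                  regimes = c("cold_drug", "cold_target",
                                              "warm")) {
  drugCfg <- ginEncoderConfig(hiddenDim = hiddenDim,
                              readoutHidden = hiddenDim,
                              outputDim = encoderDim)
  protCfg <- sequenceEncoderConfig(embeddingDim = embeddingDim,
                                   outputDim = encoderDim)
  rows <- list()
  for (s in seeds) {
    base <- deriveSeed(rootSeed, 10000L + s)
    wc <- worldConfig
    wc$seed <- deriveSeed(base, 1L)
    world <- generateWorld(wc)
    graphs <- suppressWarnings(
      parseSmilesSet(setNames(world@chemicals$smiles, world@chemicals$id)))$graphs
    cci <- sampleInteractionPairs(world, "cci", nCci, seed = deriveSeed(base, 2L))
    ppi <- sampleInteractionPairs(world, "ppi", nPpi, seed = deriveSeed(base, 3L))
    dta <- sampleDtaPairs(world, nDta, seed = deriveSeed(base, 4L))

    ptc <- trainConfig(learningRate = learningRate, batchSize = Inf,
                       epochs = pretrainEpochs, seed = deriveSeed(base, 5L),
                       evalEvery = 10L, headHidden = 64L, patience = 15L)
    drugState <- pretrainEncoder(cci, drugCfg, ptc, graphs = graphs)$state
    ptc$seed <- deriveSeed(base, 6L)
    protState <- pretrainEncoder(ppi, protCfg, ptc)$state

    arms <- list(
      cold_drug = list(pretrained = list(drugState, NULL),
                       scratch = list(NULL, NULL)),
      cold_target = list(pretrained = list(NULL, protState),
                         scratch = list(NULL, NULL)),
      warm = list(drug_pretrained = list(drugState, NULL),
                  protein_pretrained = list(NULL, protState),
                  scratch = list(NULL, NULL)))
    for (regime in regimes) {
      split <- coldSplit(dta, regime, seed = deriveSeed(base, 7L))
      for (arm in names(arms[[regime]])) {
        st <- arms[[regime]][[arm]]
        model <- assembleDtaModel(drugCfg, protCfg, drugState = st[[1]],
                                  proteinState = st[[2]],
                                  seed = deriveSeed(base, 8L))
        pretrainedArm <- !is.null(st[[1]]) || !is.null(st[[2]])
        modes <- if (!pretrainedArm) "from_scratch"
                 else if (identical(dtaMode, "select"))
                   c("transfer_finetune", "transfer_frozen")
                 else dtaMode
        best <- NULL
        for (mode in modes) {
          tc <- trainConfig(learningRate = learningRate, batchSize = Inf,
                            epochs = dtaEpochs, seed = deriveSeed(base, 9L),
                            evalEvery = 10L, encoderMode = mode,
                            patience = 15L)
          res <- trainDta(model, split, dta, tc, graphs = graphs)
          vloss <- res$metrics$value[res$metrics$split == "valid" &
                                       res$metrics$metric == "rmse"]
          if (is.null(best) || vloss < best$vloss)
            best <- list(res = res, vloss = vloss, mode = mode)
        }
        m <- best$res$metrics[best$res$metrics$split == "test", ]
        rows[[length(rows) + 1L]] <- data.frame(
          seed = s, regime = regime, arm = arm, mode = best$mode,
          metric = m$metric, value = m$value, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  list(results = results, summary = summarizeTransfer(results))
}

#' Summarize a transfer experiment
#'
#' Win counts (replicates where the pretrained arm's test RMSE beats the
#' scratch arm's) and seed-mean RMSE gaps (scratch minus pretrained; positive
#' means pretraining helped) per regime, including the warm-regime gaps for
#' each pretrained encoder.
#'
#' @param results the `results` data.frame of [runTransferExperiment()].
#' @return Named list of win counts, replicate counts and mean gaps.
#' @export
summarizeTransfer <- function(results) {
  r <- results[results$metric == "rmse", ]
  get <- function(regime, arm) {
    d <- r[r$regime == regime & r$arm == arm, ]
    setNames(d$value, d$seed)
  }
  out <- list()
  if ("cold_drug" %in% r$regime) {
    pre <- get("cold_drug", "pretrained"); scr <- get("cold_drug", "scratch")
    scr <- scr[names(pre)]
    out$coldDrugWins <- sum(pre < scr)
    out$coldDrugN <- length(pre)
    out$coldDrugGap <- mean(scr - pre)
  }
  if ("cold_target" %in% r$regime) {
    pre <- get("cold_target", "pretrained"); scr <- get("cold_target", "scratch")
    scr <- scr[names(pre)]
    out$coldTargetWins <- sum(pre < scr)
    out$coldTargetN <- length(pre)
    out$coldTargetGap <- mean(scr - pre)
  }
  if ("warm" %in% r$regime) {
    scr <- get("warm", "scratch")
    dpre <- get("warm", "drug_pretrained")[names(scr)]
    ppre <- get("warm", "protein_pretrained")[names(scr)]
    out$warmDrugGap <- mean(scr - dpre)
    out$warmProteinGap <- mean(scr - ppre)
  }
  out
}
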