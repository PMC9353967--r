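#' Training configuration
#'
#' Hyper-parameters of the Adam training loops. The tuned ranges behind the
#' defaults are learning rate in [0.0005, 0.005] and batch size in
#' {128, 256, 512, 1024}; `batchSize = Inf` requests full-batch steps. Epoch
#' selection follows the validation loss (`select = "best"`, the default) or
#' takes the final epoch (`"last"`); `patience` stops training after that
#' many epochs without validation improvement. `epochs = 0` is allowed and
#' returns the initialization untouched (useful as a contract check).
#'
#' @param learningRate Adam step size (> 0; default 0.001).
#' @param batchSize minibatch size, or Inf for full-batch (default 512).
#' @param epochs maximum training epochs (default 500, the regression-task
#'   recipe).
#' @param seed integer seed fanned out to init, shuffling and splits.
#' @param patience early-stopping patience on validation loss (default Inf:
#'   off).
#' @param select "best" (validation-selected epoch) or "last".
#' @param encoderMode "transfer_finetune" (default: transferred encoders keep
#'   training on the downstream task), "transfer_frozen" (transferred
#'   encoders fixed) or "from_scratch".
#' @param validFraction fraction of pretraining pairs held out for
#'   validation (default 0.1).
#' @param headHidden optional hidden width override for task heads.
#' @param evalEvery validate every this many epochs (default 1; larger
#'   values trade selection granularity for speed on long runs).
#' @return A named list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 0.001, batchSize = 512, epochs = 500L,
                        seed = 1L, patience = Inf,
                        select = c("best", "last"),
                        encoderMode = c("transfer_finetune", "transfer_frozen",
                                        "from_scratch"),
                        validFraction = 0.1, headHidden = NULL,
                        evalEvery = 1L) {
  stopIfNot(learningRate > 0, "learningRate must be > 0")
  stopIfNot(epochs >= 0, "epochs must be >= 0")
  cfg <- list(learningRate = learningRate, batchSize = batchSize,
              epochs = as.integer(epochs), seed = as.integer(seed),
              patience = patience, select = match.arg(select),
              encoderMode = match.arg(encoderMode),
              validFraction = validFraction, headHidden = headHidden,
              evalEvery = as.integer(evalEvery))
  class(cfg) <- c("TrainConfig", "list")
  cfg
}

# ---- entity encoder closures -------------------------------------------------
# Uniform interface over the two encoder kinds so the training loops do not
# branch: forward(params, idx, keepCache) -> list(out, cache);
# backward(params, cache, dOut) -> grads.

makeEntityEncoder <- function(cfg, store, graphs = NULL) {
  if (cfg$kind == "gin") {
    if (is.null(graphs)) {
      parsed <- parseSmilesSet(store)
      if (length(parsed$failed))
        stop("unparsable SMILES among entities: ",
             paste(head(parsed$failed, 5L), collapse = ", "), call. = FALSE)
      graphs <- parsed$graphs
    }
    stopIfNot(all(names(store) %in% names(graphs)),
              "graph cache does not cover all entities")
    graphs <- graphs[names(store)]
    batchCache <- new.env(parent = emptyenv())
    getBatch <- function(idx) {
      key <- paste(idx, collapse = ".")
      b <- batchCache[[key]]
      if (is.null(b)) {
        b <- graphBatch(graphs[idx])
        if (length(ls(batchCache)) < 8L) batchCache[[key]] <- b
      }
      b
    }
    list(
      forward = function(params, idx, keepCache = FALSE)
        ginForwardBatch(params, getBatch(idx), cfg, keepCache),
      backward = function(params, cache, dOut)
        ginBackwardBatch(params, cache, dOut, cfg))
  } else {
    comp <- compositionMatrix(store, cfg$vocab)
    list(
      forward = function(params, idx, keepCache = FALSE)
        seqForwardComp(params, comp[idx, , drop = FALSE], cfg, keepCache),
      backward = function(params, cache, dOut)
        seqBackwardComp(params, cache, dOut))
  }
}

scatterRows <- function(dJ, localIdx, nUnique) {
  acc <- rowsum(dJ, localIdx)
  out <- matrix(0, nUnique, ncol(dJ))
  out[as.integer(rownames(acc)), ] <- acc
  out
}

makeBatches <- function(n, batchSize) {
  if (!is.finite(batchSize) || batchSize >= n) return(list(seq_len(n)))
  split(seq_len(n), ceiling(seq_len(n) / batchSize))
}

# ---- pretraining -------------------------------------------------------------

#' Pretrain an encoder on a pairwise interaction task
#'
#' Siamese training: one shared encoder maps both members of each pair to
#' d'-vectors, the concatenation passes through a classification head, and
#' binary cross-entropy is minimized with Adam. An internal validation split
#' tracks per-epoch loss and AUC (concordance of scores with the 0/1
#' labels); the returned encoder parameters are those of the best validation
#' epoch under `config$select = "best"`.
#'
#' @param dataset a CCI or PPI [PairDataset-class]. CCI pairs require a
#'   chemical encoder (GIN graphs or SMILES-token sequence encoder); PPI
#'   pairs require a protein sequence encoder. Mismatches error before any
#'   training.
#' @param encoderConfig a [ginEncoderConfig()] or [sequenceEncoderConfig()].
#' @param config a [trainConfig()].
#' @param graphs optional named list of pre-parsed [MoleculeGraph-class]
#'   objects keyed by chemical id (avoids re-parsing between runs).
#' @param standardize standardize the returned encoder's outputs to zero
#'   mean and unit variance over the pretraining entities (default TRUE).
#'   Siamese classification inflates encoder output scale (larger logits
#'   mean lower loss), which puts transferred features on an arbitrary
#'   scale; the standardization folds a per-dimension affine correction
#'   into the final readout layer, changing nothing about the information
#'   content.
#' @return A list with `state` (the pretrained [EncoderState-class]), `head`
#'   (classifier head parameters), `log` (per-epoch data.frame: epoch, split,
#'   loss, auc) and `bestEpoch`.
#' @export
pretrainEncoder <- function(dataset, encoderConfig, config = trainConfig(),
                            graphs = NULL, standardize = TRUE) {
  stopIfNot(is(dataset, "PairDataset") && dataset@task %in% c("cci", "ppi"),
            "pretraining expects a CCI or PPI dataset")
  store <- if (dataset@task == "cci") dataset@chemicals else dataset@proteins
  stopIfNot(length(store) > 0L, "dataset has an empty entity store")
  if (encoderConfig$kind == "gin" && dataset@task != "cci")
    stop("a GIN encoder consumes molecules; it cannot pretrain on PPI pairs",
         call. = FALSE)
  pairs <- dataset@pairs
  stopIfNot(nrow(pairs) > 0L, "dataset is empty")
  ids <- names(store)
  li <- match(pairs$left, ids)
  ri <- match(pairs$right, ids)
  y <- as.numeric(pairs$label)

  enc <- makeEntityEncoder(encoderConfig, store, graphs)
  state0 <- initEncoderState(encoderConfig, config$seed)
  headCfg <- pairHeadConfig(inputDim = encoderConfig$outputDim,
                            hidden = config$headHidden %||%
                              (2L * encoderConfig$outputDim),
                            task = dataset@task)
  params <- c(prefixNames(state0@params, "enc."),
              prefixNames(initHeadParams(headCfg, config$seed), "head."))

  n <- nrow(pairs)
  set.seed(deriveSeed(config$seed, 31L))
  perm <- sample.int(n)
  nVal <- max(1L, floor(config$validFraction * n))
  validIdx <- perm[seq_len(nVal)]
  trainIdx <- perm[(nVal + 1L):n]

  evalSplit <- function(params, idx) {
    uid <- sort(unique(c(li[idx], ri[idx])))
    Xe <- enc$forward(stripPrefix(params, "enc."), uid)$out
    J <- cbind(Xe[match(li[idx], uid), , drop = FALSE],
               Xe[match(ri[idx], uid), , drop = FALSE])
    o <- drop(headForwardBatch(stripPrefix(params, "head."), J, headCfg)$out)
    auc <- if (length(idx) >= 2L && length(unique(y[idx])) == 2L)
      suppressWarnings(concordanceIndex(o, y[idx])) else NA_real_
    list(loss = mean(softplus(o) - y[idx] * o), auc = auc)
  }

  opt <- adamInit(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- list()
  sinceBest <- 0L
  for (epoch in seq_len(config$epochs)) {
    set.seed(deriveSeed(config$seed, 1000L + epoch))
    shuffled <- trainIdx[sample.int(length(trainIdx))]
    epochLoss <- 0
    for (b in makeBatches(length(shuffled), config$batchSize)) {
      idx <- shuffled[b]
      uid <- sort(unique(c(li[idx], ri[idx])))
      encP <- stripPrefix(params, "enc.")
      headP <- stripPrefix(params, "head.")
      fw <- enc$forward(encP, uid, keepCache = TRUE)
      lloc <- match(li[idx], uid)
      rloc <- match(ri[idx], uid)
      J <- cbind(fw$out[lloc, , drop = FALSE], fw$out[rloc, , drop = FALSE])
      hf <- headForwardBatch(headP, J, headCfg, keepCache = TRUE)
      o <- drop(hf$out)
      nb <- length(idx)
      epochLoss <- epochLoss + sum(softplus(o) - y[idx] * o)
      dO <- matrix((sigmoid(o) - y[idx]) / nb, ncol = 1L)
      hb <- headBackwardBatch(headP, hf$cache, dO, headCfg)
      dp <- ncol(fw$out)
      dXe <- scatterRows(hb$dJ[, seq_len(dp), drop = FALSE], lloc, length(uid)) +
        scatterRows(hb$dJ[, dp + seq_len(dp), drop = FALSE], rloc, length(uid))
      gEnc <- enc$backward(encP, fw$cache, dXe)
      grads <- c(prefixNames(gEnc, "enc."), prefixNames(hb$grads, "head."))
      upd <- adamStep(params, grads, opt, config$learningRate)
      params <- upd$params
      opt <- upd$state
    }
    if (epoch %% config$evalEvery == 0L || epoch == config$epochs) {
      val <- evalSplit(params, validIdx)
      log[[length(log) + 1L]] <- data.frame(
        epoch = epoch, split = c("train", "valid"),
        loss = c(epochLoss / length(trainIdx), val$loss),
        auc = c(NA_real_, val$auc))
      if (val$loss < best$loss) {
        best <- list(loss = val$loss, params = params, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$patience) break
      }
    }
  }
  final <- if (config$select == "best" && best$epoch > 0L) best$params else params
  encFinal <- stripPrefix(final, "enc.")
  if (standardize && config$epochs > 0L) {
    X <- enc$forward(encFinal, seq_along(ids))$out
    mu <- colMeans(X)
    sdv <- pmax(apply(X, 2, sd), 1e-8)
    outW <- if (encoderConfig$kind == "gin") "R.W1" else "P.W"
    outB <- if (encoderConfig$kind == "gin") "R.b1" else "P.b"
    encFinal[[outW]] <- sweep(encFinal[[outW]], 2, sdv, "/")
    encFinal[[outB]] <- (encFinal[[outB]] - mu) / sdv
  }
  state <- new("EncoderState", kind = encoderConfig$kind,
               params = encFinal,
               config = unclass(encoderConfig),
               fingerprint = configFingerprint(encoderConfig))
  list(state = state, head = stripPrefix(final, "head."),
       log = do.call(rbind, log) %||% data.frame(),
       bestEpoch = if (config$select == "best") best$epoch else config$epochs)
}

# ---- DTA assembly and training ----------------------------------------------

checkTransfer <- function(state, cfg, what) {
  if (is.null(state)) return(invisible())
  stopIfNot(is(state, "EncoderState"), paste(what, "state must be an EncoderState"))
  if (!identical(state@fingerprint, configFingerprint(cfg))) {
    bad <- configDiff(state@config, unclass(cfg))
    stop(sprintf("%s encoder checkpoint does not match the model config; divergent fields: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Assemble a DTA model from (optionally) pretrained encoders
#'
#' Builds the affinity model of the transfer pipeline: a drug encoder, a
#' protein encoder and a fresh regression head. Either encoder may be
#' initialized from a pretraining checkpoint — its configuration fingerprint
#' must match the model configuration, otherwise assembly refuses and names
#' the divergent fields — or freshly from the seed (the from-scratch
#' baseline arms).
#'
#' @param drugConfig,proteinConfig encoder configurations; their `outputDim`
#'   must agree (the head concatenates both branches).
#' @param drugState,proteinState optional pretrained [EncoderState-class]
#'   checkpoints.
#' @param headConfig optional [pairHeadConfig()] for the regression head.
#' @param seed integer seed for all fresh parameters.
#' @return A [DtaModel-class].
#' @export
assembleDtaModel <- function(drugConfig, proteinConfig, drugState = NULL,
                             proteinState = NULL, headConfig = NULL,
                             seed = 1L) {
  stopIfNot(drugConfig$outputDim == proteinConfig$outputDim,
            "drug and protein encoders must share outputDim")
  checkTransfer(drugState, drugConfig, "drug")
  checkTransfer(proteinState, proteinConfig, "protein")
  drugEnc <- drugState %||% initEncoderState(drugConfig, deriveSeed(seed, 41L))
  protEnc <- proteinState %||% initEncoderState(proteinConfig, deriveSeed(seed, 42L))
  headCfg <- headConfig %||% pairHeadConfig(inputDim = drugConfig$outputDim,
                                            task = "dta")
  head <- initHeadParams(headCfg, deriveSeed(seed, 43L))
  new("DtaModel", drugEncoder = drugEnc, proteinEncoder = protEnc,
      head = head, headConfig = unclass(headCfg),
      info = list(drugOrigin = if (is.null(drugState)) "fresh" else "pretrained",
                  proteinOrigin = if (is.null(proteinState)) "fresh" else "pretrained",
                  drugInit = drugState, proteinInit = proteinState,
                  drugConfig = unclass(drugConfig),
                  proteinConfig = unclass(proteinConfig),
                  seed = as.integer(seed)))
}

#' Train the affinity regressor
#'
#' Minimizes mean squared error on the training partition of `split` with
#' Adam (labels are centered on the training mean during optimization and
#' the offset restored at prediction time), monitors validation loss each
#' epoch, restores the
#' validation-selected parameters (under `config$select = "best"`) and
#' reports test-set RMSE, Pearson, Spearman and concordance index. Under
#' `config$encoderMode = "transfer_frozen"` any encoder that was transferred
#' from a pretraining checkpoint is excluded from the updates;
#' "transfer_finetune" (default) trains everything.
#'
#' With `replicateSeeds`, the model is re-assembled and re-trained once per
#' seed (transferred checkpoints stay fixed; fresh parameters and data order
#' re-draw), and the report carries one metrics row per run plus their mean
#' and standard deviation.
#'
#' @param model a [DtaModel-class] from [assembleDtaModel()].
#' @param split a [SplitManifest-class] covering `dataset`.
#' @param dataset a DTA [PairDataset-class].
#' @param config a [trainConfig()].
#' @param graphs optional pre-parsed graph list keyed by chemical id.
#' @param replicateSeeds optional integer vector of replicate seeds.
#' @return A list with `model` (trained), `metrics` (data.frame run, split,
#'   metric, value), `summary` (data.frame metric, mean, sd on test), `log`
#'   (per-epoch losses) and `predictions` (test-set data.frame).
#' @export
trainDta <- function(model, split, dataset, config = trainConfig(),
                     graphs = NULL, replicateSeeds = NULL) {
  stopIfNot(is(dataset, "PairDataset") && dataset@task == "dta",
            "trainDta expects a DTA dataset")
  audit <- auditSplit(split, dataset)
  stopIfNot(audit$covers && audit$disjointRecords,
            "split does not cover the dataset with disjoint partitions")
  stopIfNot(length(split@train) > 0L, "empty training partition")
  if (is.null(replicateSeeds)) {
    res <- trainDtaOnce(model, split, dataset, config, graphs)
    res$metrics <- cbind(run = 1L, res$metrics)
    return(res)
  }
  runs <- vector("list", length(replicateSeeds))
  for (k in seq_along(replicateSeeds)) {
    s <- replicateSeeds[k]
    mk <- assembleDtaModel(model@info$drugConfig, model@info$proteinConfig,
                           drugState = model@info$drugInit,
                           proteinState = model@info$proteinInit,
                           headConfig = model@headConfig, seed = s)
    cfg <- config; cfg$seed <- as.integer(s)
    runs[[k]] <- trainDtaOnce(mk, split, dataset, cfg, graphs)
  }
  metrics <- do.call(rbind, lapply(seq_along(runs), function(k)
    cbind(run = k, runs[[k]]$metrics)))
  test <- metrics[metrics$split == "test", ]
  summary <- do.call(rbind, lapply(split(test, test$metric), function(d)
    data.frame(metric = d$metric[1], mean = mean(d$value), sd = sd(d$value))))
  rownames(summary) <- NULL
  list(model = runs[[length(runs)]]$model, metrics = metrics,
       summary = summary, log = runs[[length(runs)]]$log,
       predictions = runs[[length(runs)]]$predictions, runs = runs)
}

trainDtaOnce <- function(model, split, dataset, config, graphs = NULL) {
  pairs <- dataset@pairs
  drugStore <- dataset@chemicals
  protStore <- dataset@proteins
  di <- match(pairs$left, names(drugStore))
  pj <- match(pairs$right, names(protStore))
  # center labels on the training mean so the head starts at the train-mean
  # predictor; the offset is stored on the model and added back at inference
  labelOffset <- mean(as.numeric(pairs$label)[split@train])
  y <- as.numeric(pairs$label) - labelOffset

  drugCfg <- model@info$drugConfig
  protCfg <- model@info$proteinConfig
  headCfg <- model@headConfig
  drugEnc <- makeEntityEncoder(drugCfg, drugStore, graphs)
  protEnc <- makeEntityEncoder(protCfg, protStore)

  params <- c(prefixNames(model@drugEncoder@params, "drug."),
              prefixNames(model@proteinEncoder@params, "prot."),
              prefixNames(model@head, "head."))
  frozen <- character()
  drugFrozen <- protFrozen <- FALSE
  if (config$encoderMode == "transfer_frozen") {
    if (identical(model@info$drugOrigin, "pretrained")) {
      frozen <- c(frozen, grep("^drug\\.", names(params), value = TRUE))
      drugFrozen <- TRUE
    }
    if (identical(model@info$proteinOrigin, "pretrained")) {
      frozen <- c(frozen, grep("^prot\\.", names(params), value = TRUE))
      protFrozen <- TRUE
    }
  }

  trainIdx <- split@train
  validIdx <- split@valid
  testIdx <- split@test

  forwardIdx <- function(params, idx) {
    ud <- sort(unique(di[idx])); up <- sort(unique(pj[idx]))
    Xd <- drugEnc$forward(stripPrefix(params, "drug."), ud)$out
    Xp <- protEnc$forward(stripPrefix(params, "prot."), up)$out
    J <- cbind(Xp[match(pj[idx], up), , drop = FALSE],
               Xd[match(di[idx], ud), , drop = FALSE])
    drop(headForwardBatch(stripPrefix(params, "head."), J, headCfg)$out)
  }

  opt <- adamInit(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- list()
  sinceBest <- 0L
  for (epoch in seq_len(config$epochs)) {
    set.seed(deriveSeed(config$seed, 2000L + epoch))
    shuffled <- trainIdx[sample.int(length(trainIdx))]
    epochLoss <- 0
    for (b in makeBatches(length(shuffled), config$batchSize)) {
      idx <- shuffled[b]
      ud <- sort(unique(di[idx])); up <- sort(unique(pj[idx]))
      drugP <- stripPrefix(params, "drug.")
      protP <- stripPrefix(params, "prot.")
      headP <- stripPrefix(params, "head.")
      fd <- drugEnc$forward(drugP, ud, keepCache = !drugFrozen)
      fp <- protEnc$forward(protP, up, keepCache = !protFrozen)
      dloc <- match(di[idx], ud); ploc <- match(pj[idx], up)
      J <- cbind(fp$out[ploc, , drop = FALSE], fd$out[dloc, , drop = FALSE])
      hf <- headForwardBatch(headP, J, headCfg, keepCache = TRUE)
      o <- drop(hf$out)
      nb <- length(idx)
      epochLoss <- epochLoss + sum((o - y[idx])^2)
      dO <- matrix(2 * (o - y[idx]) / nb, ncol = 1L)
      hb <- headBackwardBatch(headP, hf$cache, dO, headCfg)
      dp <- ncol(fd$out)
      grads <- prefixNames(hb$grads, "head.")
      if (!drugFrozen) {
        dXd <- scatterRows(hb$dJ[, dp + seq_len(dp), drop = FALSE], dloc,
                           length(ud))
        grads <- c(grads,
                   prefixNames(drugEnc$backward(drugP, fd$cache, dXd), "drug."))
      }
      if (!protFrozen) {
        dXp <- scatterRows(hb$dJ[, seq_len(dp), drop = FALSE], ploc,
                           length(up))
        grads <- c(grads,
                   prefixNames(protEnc$backward(protP, fp$cache, dXp), "prot."))
      }
      upd <- adamStep(params, grads, opt, config$learningRate, skip = frozen)
      params <- upd$params
      opt <- upd$state
    }
    if (epoch %% config$evalEvery == 0L || epoch == config$epochs) {
      valPred <- forwardIdx(params, validIdx)
      valLoss <- mean((valPred - y[validIdx])^2)
      log[[length(log) + 1L]] <- data.frame(
        epoch = epoch, trainLoss = epochLoss / length(trainIdx),
        validLoss = valLoss)
      if (valLoss < best$loss) {
        best <- list(loss = valLoss, params = params, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$patience) break
      }
    }
  }
  final <- if (config$select == "best" && best$epoch > 0L) best$params else params

  testPred <- forwardIdx(final, testIdx) + labelOffset
  validPred <- forwardIdx(final, validIdx) + labelOffset
  metrics <- rbind(
    metricsRows("valid", validPred, y[validIdx] + labelOffset),
    metricsRows("test", testPred, y[testIdx] + labelOffset))

  trained <- model
  trained@drugEncoder@params <- stripPrefix(final, "drug.")
  trained@proteinEncoder@params <- stripPrefix(final, "prot.")
  trained@head <- stripPrefix(final, "head.")
  trained@info$log <- do.call(rbind, log) %||% data.frame()
  trained@info$bestEpoch <- best$epoch
  trained@info$labelOffset <- labelOffset
  list(model = trained,
       metrics = metrics,
       summary = data.frame(metric = metrics$metric[metrics$split == "test"],
                            mean = metrics$value[metrics$split == "test"],
                            sd = NA_real_),
       log = trained@info$log,
       predictions = data.frame(left = pairs$left[testIdx],
                                right = pairs$right[testIdx],
                                label = y[testIdx] + labelOffset,
                                prediction = testPred,
                                stringsAsFactors = FALSE))
}

metricsRows <- function(split, pred, lab) {
  data.frame(split = split,
             metric = c("rmse", "pearson", "spearman", "ci"),
             value = c(rmse(pred, lab),
                       suppressWarnings(pearsonR(pred, lab)),
                       suppressWarnings(spearmanRho(pred, lab)),
                       suppressWarnings(concordanceIndex(pred, lab))),
             stringsAsFactors = FALSE)
}

#' Predict affinities for a DTA dataset
#'
#' Forward pass of a (trained) model over the given record indices.
#'
#' @param model a [DtaModel-class].
#' @param dataset a DTA [PairDataset-class].
#' @param indices record indices (default: all records).
#' @param graphs optional pre-parsed graph list.
#' @return Numeric affinity predictions.
#' @export
predictDta <- function(model, dataset, indices = NULL, graphs = NULL) {
  stopIfNot(dataset@task == "dta", "predictDta expects a DTA dataset")
  pairs <- dataset@pairs
  indices <- indices %||% seq_len(nrow(pairs))
  drugEnc <- makeEntityEncoder(model@info$drugConfig, dataset@chemicals, graphs)
  protEnc <- makeEntityEncoder(model@info$proteinConfig, dataset@proteins)
  di <- match(pairs$left, names(dataset@chemicals))[indices]
  pj <- match(pairs$right, names(dataset@proteins))[indices]
  ud <- sort(unique(di)); up <- sort(unique(pj))
  Xd <- drugEnc$forward(model@drugEncoder@params, ud)$out
  Xp <- protEnc$forward(model@proteinEncoder@params, up)$out
  J <- cbind(Xp[match(pj, up), , drop = FALSE],
             Xd[match(di, ud), , drop = FALSE])
  drop(headForwardBatch(model@head, J, model@headConfig)$out) +
    (model@info$labelOffset %||% 0)
}
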