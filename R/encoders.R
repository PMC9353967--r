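#' GIN graph-encoder configuration
#'
#' A stack of `numLayers` graph-isomorphism-network layers. Each layer
#' updates node features as `MLP((1 + eps) * p_v + sum of neighbour p_u)`
#' with a trainable scalar `eps` (initialized at `epsilonInit`) and a
#' two-layer MLP (affine, ReLU, affine) of width `hiddenDim`; there is no
#' degree normalization. After the last layer, node features are max-pooled
#' coordinate-wise over the molecule and projected by two affine readout
#' layers (`readoutHidden` wide, then `outputDim`). Two stacked affine maps
#' with no activation collapse into one, so a ReLU between them is the
#' default; `readoutActivation = "none"` gives the strictly linear readout.
#'
#' @param numLayers number of GIN layers (default 5).
#' @param hiddenDim width of each layer and of its internal MLP.
#' @param readoutHidden width of the first readout affine map.
#' @param outputDim encoder output length d' (default 128).
#' @param nodeFeatureDim input node-feature length (default 74, matching
#'   [atomFeatureConfig()]).
#' @param epsilonInit initial value of each layer's trainable epsilon.
#' @param readoutActivation "relu" (default) or "none" between the two
#'   readout affine maps.
#' @return A named list of class `GinEncoderConfig`.
#' @export
ginEncoderConfig <- function(numLayers = 5L, hiddenDim = 32L,
                             readoutHidden = 32L, outputDim = 128L,
                             nodeFeatureDim = 74L, epsilonInit = 0,
                             readoutActivation = c("relu", "none")) {
  stopIfNot(numLayers >= 1L, "numLayers must be >= 1")
  stopIfNot(outputDim >= 1L, "outputDim must be >= 1")
  cfg <- list(kind = "gin", numLayers = as.integer(numLayers),
              hiddenDim = as.integer(hiddenDim),
              readoutHidden = as.integer(readoutHidden),
              outputDim = as.integer(outputDim),
              nodeFeatureDim = as.integer(nodeFeatureDim),
              epsilonInit = as.numeric(epsilonInit),
              readoutActivation = match.arg(readoutActivation))
  class(cfg) <- c("GinEncoderConfig", "list")
  cfg
}

#' Sequence-encoder configuration
#'
#' Token sequences (amino acids for proteins, characters for SMILES) are
#' mapped by a token-embedding provider to an n x d matrix, averaged over the
#' n tokens, and projected by a single affine layer from d to d' < d. The
#' default provider is a trainable per-token lookup table; external
#' transformer language models plug in through the same provider contract
#' (tokens in, n x d matrix out) and are frozen by default, used purely as
#' feature extractors.
#'
#' @param providerName identifier of the embedding provider ("lookup" for the
#'   built-in trainable table).
#' @param vocab token vocabulary; must contain the unknown token "X".
#' @param embeddingDim provider embedding width d (default 768).
#' @param outputDim projection output d' (default 128); must be < d.
#' @param providerTrainable whether provider embeddings are trained (TRUE for
#'   the lookup table, which has no pretraining of its own; FALSE for
#'   external providers).
#' @return A named list of class `SequenceEncoderConfig`.
#' @export
sequenceEncoderConfig <- function(providerName = "lookup",
                                  vocab = aminoAcidVocab(),
                                  embeddingDim = 768L, outputDim = 128L,
                                  providerTrainable = providerName == "lookup") {
  stopIfNot(outputDim < embeddingDim,
            "outputDim must be smaller than embeddingDim (projection contract)")
  stopIfNot("X" %in% vocab, "vocab must contain the unknown token 'X'")
  cfg <- list(kind = "sequence", providerName = providerName,
              vocab = as.character(vocab),
              embeddingDim = as.integer(embeddingDim),
              outputDim = as.integer(outputDim),
              providerTrainable = isTRUE(providerTrainable))
  class(cfg) <- c("SequenceEncoderConfig", "list")
  cfg
}

#' Token vocabularies
#'
#' `aminoAcidVocab`: the 20 standard residues plus the unknown token "X".
#' `smilesVocab`: the characters of the organic-subset SMILES grammar plus
#' "X" for anything else.
#' @return Character vector of tokens.
#' @export
aminoAcidVocab <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
}

#' @rdname aminoAcidVocab
#' @export
smilesVocab <- function() {
  c(strsplit("CNOSPFIBcnos", "")[[1]], "l", "r", "(", ")", "=", "#",
    "1", "2", "3", "4", "[", "]", "@", "+", "-", "/", "\\", ".", "X")
}

#' Tokenize a sequence against a vocabulary
#'
#' Splits into single characters; tokens outside the vocabulary map to the
#' unknown token "X" with a warning.
#'
#' @param sequence a single string.
#' @param vocab character vector of tokens containing "X".
#' @return Integer vector of token indices into `vocab`.
#' @export
tokenizeSequence <- function(sequence, vocab = aminoAcidVocab()) {
  stopIfNot(is.character(sequence) && length(sequence) == 1L && nzchar(sequence),
            "sequence must be a single non-empty string")
  toks <- strsplit(sequence, "")[[1]]
  idx <- match(toks, vocab)
  if (anyNA(idx)) {
    warning(sprintf("%d tokens outside the vocabulary mapped to 'X'",
                    sum(is.na(idx))))
    idx[is.na(idx)] <- match("X", vocab)
  }
  idx
}

# normalized token-count (composition) matrix, one row per sequence
compositionMatrix <- function(sequences, vocab) {
  M <- matrix(0, length(sequences), length(vocab),
              dimnames = list(names(sequences), vocab))
  for (i in seq_along(sequences)) {
    idx <- suppressWarnings(tokenizeSequence(sequences[[i]], vocab))
    tb <- tabulate(idx, nbins = length(vocab))
    M[i, ] <- tb / length(idx)
  }
  M
}

#' Token-embedding provider constructors
#'
#' A provider is a function mapping a token-index vector of length n to an
#' n x d embedding matrix; it must be deterministic given fixed parameters
#' and emit one row per input token. `lookupProvider` builds the provider
#' view of a trainable lookup table; `matrixProvider` wraps any fixed
#' per-token embedding matrix (e.g. rows precomputed by an external language
#' model), frozen by construction.
#'
#' @param E numeric matrix, vocabulary size x d.
#' @return A function `f(tokenIndices) -> n x d matrix` with class
#'   `TokenEmbeddingProvider`.
#' @export
lookupProvider <- function(E) {
  f <- function(tokens) E[tokens, , drop = FALSE]
  class(f) <- c("TokenEmbeddingProvider", "function")
  f
}

#' @rdname lookupProvider
#' @export
matrixProvider <- lookupProvider

#' Initialize an encoder state
#'
#' Draws fresh parameters for the encoder described by `config` (a
#' [ginEncoderConfig()] or [sequenceEncoderConfig()]) under `seed` and wraps
#' them with the config fingerprint used to validate transfer.
#'
#' @param config encoder configuration.
#' @param seed integer seed.
#' @return An [EncoderState-class].
#' @export
initEncoderState <- function(config, seed = 1L) {
  set.seed(deriveSeed(seed, 11L))
  params <- switch(config$kind,
    gin = ginInitParams(config),
    sequence = seqInitParams(config),
    stop("unknown encoder kind: ", config$kind))
  new("EncoderState", kind = config$kind, params = params,
      config = unclass(config), fingerprint = configFingerprint(config))
}

#' One GIN layer update
#'
#' Computes `MLP((1 + epsilon) * X + A X)` for all nodes at once: sum
#' aggregation over neighbours plus the epsilon-weighted self term, with no
#' degree normalization, then the layer map.
#'
#' @param nodeFeatures numeric matrix N x C.
#' @param adjacency symmetric binary N x N matrix.
#' @param epsilon scalar self-loop weight.
#' @param mlp either a function `matrix -> matrix` (e.g. `identity`) or a
#'   parameter list with `W1`, `b1`, `W2`, `b2` applying
#'   affine-ReLU-affine.
#' @return Numeric matrix N x C'.
#' @examples
#' X <- matrix(c(1, 2, 3), 3, 1)
#' A <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3) # 3-cycle
#' ginLayer(X, A, epsilon = 0.5, mlp = identity)   # node 1: 1.5*1 + 2 + 3
#' @export
ginLayer <- function(nodeFeatures, adjacency, epsilon = 0, mlp = identity) {
  stopIfNot(is.matrix(nodeFeatures) && all(is.finite(nodeFeatures)),
            "nodeFeatures must be a finite numeric matrix")
  stopIfNot(nrow(adjacency) == nrow(nodeFeatures),
            "adjacency and nodeFeatures disagree on node count")
  stopIfNot(isTRUE(all.equal(adjacency, t(adjacency))),
            "adjacency must be symmetric")
  agg <- (1 + epsilon) * nodeFeatures + adjacency %*% nodeFeatures
  if (is.function(mlp)) return(as.matrix(mlp(agg)))
  stopIfNot(ncol(agg) == nrow(mlp$W1),
            sprintf("MLP expects %d input features, got %d",
                    nrow(mlp$W1), ncol(agg)))
  addBias(relu(addBias(agg %*% mlp$W1, mlp$b1)) %*% mlp$W2, mlp$b2)
}

#' Encode a molecule graph to a fixed-length vector
#'
#' Runs the configured GIN stack, max-pools node features coordinate-wise
#' over the molecule and applies the two-layer affine readout, yielding the
#' length-d' drug representation. Permutation of node order leaves the
#' output unchanged (sum aggregation and max pooling are both
#' permutation-invariant).
#'
#' @param graph a [MoleculeGraph-class].
#' @param state a GIN [EncoderState-class].
#' @return Numeric vector of length `outputDim`.
#' @export
encodeGraph <- function(graph, state) {
  stopIfNot(is(state, "EncoderState") && state@kind == "gin",
            "state must be a GIN EncoderState")
  validObject(graph)
  stopIfNot(ncol(graph@nodeFeatures) == state@config$nodeFeatureDim,
            "graph feature length does not match encoder config")
  batch <- graphBatch(list(graph))
  drop(ginForwardBatch(state@params, batch, state@config)$out)
}

#' Encode a token sequence to a fixed-length vector
#'
#' The provider emits one embedding row per token; rows are averaged
#' (arithmetic mean over the sequence axis) and projected by the encoder's
#' single affine layer to d'.
#'
#' @param sequence a single string.
#' @param state a sequence [EncoderState-class].
#' @param provider optional [lookupProvider()]-style function; defaults to
#'   the state's own lookup table.
#' @return Numeric vector of length `outputDim`.
#' @export
encodeSequence <- function(sequence, state, provider = NULL) {
  stopIfNot(is(state, "EncoderState") && state@kind == "sequence",
            "state must be a sequence EncoderState")
  if (is.null(provider)) {
    stopIfNot(!is.null(state@params[["E"]]),
              "state has no lookup table; supply a provider")
    provider <- lookupProvider(state@params[["E"]])
  }
  toks <- tokenizeSequence(sequence, state@config$vocab)
  emb <- provider(toks)
  stopIfNot(is.matrix(emb) && nrow(emb) == length(toks),
            "provider must return one embedding row per token")
  stopIfNot(ncol(emb) == state@config$embeddingDim,
            "provider embedding width does not match encoder config")
  xs <- colMeans(emb)
  drop(xs %*% state@params[["P.W"]] + state@params[["P.b"]])
}

#' Save / load encoder checkpoints
#'
#' Checkpoints are versioned RDS files embedding the parameters, the
#' configuration and its fingerprint; loading verifies the format version
#' and the fingerprint so that parameters can never silently attach to a
#' different architecture. Numeric content round-trips bit-exactly.
#'
#' @param state an [EncoderState-class].
#' @param path file path.
#' @return `saveEncoderState` returns `path` invisibly; `readEncoderState`
#'   the state.
#' @export
saveEncoderState <- function(state, path) {
  saveRDS(list(format = "affinitytransfer-encoder-v1", kind = state@kind,
               params = state@params, config = state@config,
               fingerprint = state@fingerprint), path)
  invisible(path)
}

#' @rdname saveEncoderState
#' @export
readEncoderState <- function(path) {
  obj <- readRDS(path)
  stopIfNot(identical(obj$format, "affinitytransfer-encoder-v1"),
            paste0("not an encoder checkpoint: ", path))
  new("EncoderState", kind = obj$kind, params = obj$params,
      config = obj$config, fingerprint = obj$fingerprint)
}
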