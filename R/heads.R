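#' Pair-head configuration
#'
#' The joint representation of a pair is the plain concatenation of the two
#' branch encodings (width 2 d'). Classification heads (CCI, PPI) map it
#' through affine - ReLU - affine - sigmoid to an interaction probability;
#' the regression head (DTA) through two affine maps (optional ReLU between)
#' to an unbounded affinity.
#'
#' A common shorthand writes the classifier as sigmoid(ReLU(Wx + b)), a
#' single affine map; taken literally it can only emit probabilities
#' >= 0.5, so the default here is the two-layer head and `literal = TRUE`
#' reproduces the single-layer form exactly for anyone who wants it.
#'
#' @param inputDim per-branch encoding width d' (default 128).
#' @param hidden hidden width of the head (default 2 * inputDim).
#' @param task "cci", "ppi" or "dta".
#' @param literal use the literal single-layer sigmoid(ReLU(Wx+b)) form.
#' @param activation "relu" (default) or "none" between the two affine maps
#'   of the non-literal head; with "none" the regression head is affine end
#'   to end.
#' @param threshold classification threshold for accuracy-style reporting.
#' @return A named list of class `PairHeadConfig`.
#' @export
pairHeadConfig <- function(inputDim = 128L, hidden = 2L * inputDim,
                           task = c("cci", "ppi", "dta"), literal = FALSE,
                           activation = c("relu", "none"), threshold = 0.5) {
  task <- match.arg(task)
  cfg <- list(inputDim = as.integer(inputDim), hidden = as.integer(hidden),
              task = task, literal = isTRUE(literal),
              activation = match.arg(activation),
              threshold = as.numeric(threshold))
  class(cfg) <- c("PairHeadConfig", "list")
  cfg
}

#' Join two branch encodings
#'
#' Ordered concatenation, left branch first: drug1;drug2 for CCI,
#' protein1;protein2 for PPI and protein;drug for DTA. The order is part of
#' the contract: `joinPair(a, b)` differs from `joinPair(b, a)` whenever the
#' inputs differ.
#'
#' @param left,right numeric vectors of equal length d'.
#' @return Numeric vector of length 2 d'.
#' @examples
#' joinPair(c(1, 2), c(3, 4)) # 1 2 3 4
#' @export
joinPair <- function(left, right) {
  stopIfNot(length(left) == length(right),
            sprintf("branch lengths differ: %d vs %d",
                    length(left), length(right)))
  c(left, right)
}

#' Classify an interaction from a joint representation
#'
#' Returns the interaction probability, strictly inside (0, 1) for finite
#' input. With all-zero parameters the output is exactly 0.5.
#'
#' @param joint numeric vector of length 2 d' (or a matrix of such rows).
#' @param params head parameter list (see [initHeadParams()]).
#' @param config the [pairHeadConfig()].
#' @return Probability vector (one per input row).
#' @export
classifyInteraction <- function(joint, params, config) {
  J <- if (is.matrix(joint)) joint else matrix(joint, 1L)
  stopIfNot(all(is.finite(J)), "joint representation must be finite")
  expect <- if (isTRUE(config$literal)) nrow(params[["O.W"]]) else nrow(params[["H.W"]])
  stopIfNot(ncol(J) == expect,
            sprintf("joint width %d does not match head input %d", ncol(J), expect))
  drop(sigmoid(headForwardBatch(params, J, config)$out))
}

#' Predict affinity from a joint representation
#'
#' Two affine maps (ReLU between unless `config$literal`), unbounded output
#' on the affinity scale of the training data.
#'
#' @inheritParams classifyInteraction
#' @return Numeric affinity vector.
#' @export
predictAffinity <- function(joint, params, config) {
  J <- if (is.matrix(joint)) joint else matrix(joint, 1L)
  stopIfNot(all(is.finite(J)), "joint representation must be finite")
  cfgReg <- config
  cfgReg$literal <- FALSE # regression head is always the two-affine form
  drop(headForwardBatch(params, J, cfgReg)$out)
}

#' Initialize head parameters
#'
#' @param config a [pairHeadConfig()].
#' @param seed integer seed.
#' @return Named parameter list.
#' @export
initHeadParams <- function(config, seed = 1L) {
  set.seed(deriveSeed(seed, 13L))
  headInitParams(config)
}

#' Task losses
#'
#' Mean squared error for affinity regression; binary cross-entropy on the
#' head probability for the CCI/PPI classification tasks.
#'
#' @param predictions numeric vector: affinities (dta) or probabilities
#'   (cci/ppi).
#' @param labels numeric vector: affinities or 0/1 labels.
#' @param task "cci", "ppi" or "dta".
#' @return Scalar loss, non-negative.
#' @examples
#' taskLoss(c(0, 0), c(1, 1), "dta")        # 1
#' taskLoss(c(0.5, 0.5), c(0, 1), "cci")    # log(2)
#' @export
taskLoss <- function(predictions, labels, task = c("dta", "cci", "ppi")) {
  task <- match.arg(task)
  stopIfNot(length(predictions) > 0L, "empty batch")
  stopIfNot(length(predictions) == length(labels),
            "predictions and labels must have equal length")
  if (task == "dta") {
    mean((predictions - labels)^2)
  } else {
    stopIfNot(all(labels %in% c(0, 1)), "classification labels must be 0/1")
    p <- pmin(pmax(predictions, 1e-12), 1 - 1e-12)
    -mean(labels * log(p) + (1 - labels) * log(1 - p))
  }
}
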