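#' @import methods
#' @importFrom stats rnorm runif plogis cor sd setNames
#' @importFrom utils head read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib AffinityTransfer, .registration = TRUE
NULL

#' Attributed molecular graph
#'
#' One molecule as a heavy-atom graph: a binary node-feature matrix (one row
#' per atom, fixed one-hot blocks for element / degree / hydrogen count /
#' implicit valence plus an aromatic bit) and a symmetric binary adjacency
#' matrix with one entry pair per bond, irrespective of bond order.
#'
#' @slot nodeFeatures numeric matrix, N x F, entries in {0,1}.
#' @slot adjacency numeric matrix, N x N, symmetric, zero diagonal.
#' @slot atoms data.frame of per-atom descriptors (element, degree, numH,
#'   implicitValence, aromatic) the features were derived from.
#' @slot smiles the source SMILES string.
#' @exportClass MoleculeGraph
setClass("MoleculeGraph",
  representation(
    nodeFeatures = "matrix",
    adjacency    = "matrix",
    atoms        = "data.frame",
    smiles       = "character"
  )
)

setValidity("MoleculeGraph", function(object) {
  msg <- character()
  A <- object@adjacency
  X <- object@nodeFeatures
  if (nrow(X) < 1L) msg <- c(msg, "graph must have at least one node")
  if (nrow(A) != nrow(X) || ncol(A) != nrow(X))
    msg <- c(msg, "adjacency dimensions must match node count")
  else {
    if (!isTRUE(all.equal(A, t(A)))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency entries must be 0/1")
  }
  if (!all(X %in% c(0, 1))) msg <- c(msg, "node features must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Labeled pairwise dataset (CCI, PPI or DTA)
#'
#' Records of (left id, right id, label) plus the entity stores needed to
#' resolve the ids: id -> SMILES for chemicals, id -> amino-acid sequence for
#' proteins. CCI records may additionally carry an evidence-channel tag
#' (experimental / similarity / text / other) so that pretraining can be
#' restricted to experimentally supported interactions.
#'
#' @slot task one of "cci", "ppi", "dta".
#' @slot pairs data.frame with columns left, right, label and, for CCI,
#'   channel.
#' @slot chemicals named character vector id -> SMILES (cci / dta).
#' @slot proteins named character vector id -> sequence (ppi / dta).
#' @exportClass PairDataset
setClass("PairDataset",
  representation(
    task      = "character",
    pairs     = "data.frame",
    chemicals = "character",
    proteins  = "character"
  )
)

setValidity("PairDataset", function(object) {
  msg <- character()
  task <- object@task
  if (!(length(task) == 1L && task %in% c("cci", "ppi", "dta")))
    return("task must be one of 'cci', 'ppi', 'dta'")
  p <- object@pairs
  if (!all(c("left", "right", "label") %in% names(p)))
    return("pairs must have columns left, right, label")
  if (task %in% c("cci", "ppi")) {
    if (!all(p$label %in% c(0, 1)))
      msg <- c(msg, "cci/ppi labels must be 0/1")
  } else if (!all(is.finite(p$label))) {
    msg <- c(msg, "dta affinities must be finite")
  }
  leftStore <- if (task == "ppi") object@proteins else object@chemicals
  rightStore <- if (task == "cci") object@chemicals else object@proteins
  bad <- setdiff(unique(c(p$left[!p$left %in% names(leftStore)],
                          p$right[!p$right %in% names(rightStore)])), character())
  if (length(bad))
    msg <- c(msg, paste0("unresolvable entity ids: ",
                         paste(head(bad, 5L), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Reproducible train/valid/test split
#'
#' Assignment of every record of a DTA dataset to one of train/valid/test
#' under a named regime. In the cold regimes the partition is made at the
#' entity level on the cold axis (drugs for cold_drug, proteins for
#' cold_target) and records follow their entity, so validation/test entities
#' never occur in training. The warm regime splits at record level.
#'
#' @slot regime "cold_drug", "cold_target" or "warm".
#' @slot fractions named numeric, train/valid/test, summing to 1.
#' @slot seed integer seed the assignment was drawn with.
#' @slot train,valid,test integer record indices.
#' @slot entities list of the entity-id sets assigned to each partition on
#'   the cold axis (empty for warm).
#' @exportClass SplitManifest
setClass("SplitManifest",
  representation(
    regime    = "character",
    fractions = "numeric",
    seed      = "integer",
    train     = "integer",
    valid     = "integer",
    test      = "integer",
    entities  = "list"
  )
)

setValidity("SplitManifest", function(object) {
  msg <- character()
  if (!object@regime %in% c("cold_drug", "cold_target", "warm"))
    msg <- c(msg, "unknown regime")
  idx <- c(object@train, object@valid, object@test)
  if (anyDuplicated(idx)) msg <- c(msg, "partitions overlap")
  if (abs(sum(object@fractions) - 1) > 1e-8)
    msg <- c(msg, "fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic chemical/protein world with shared latent structure
#'
#' Generated chemicals (fragment-grammar SMILES) and proteins (motif-bearing
#' sequences) whose latent interaction vectors are deterministic functions of
#' their observable structure: normalized fragment counts times fragment
#' loadings for chemicals, normalized motif counts times motif loadings for
#' proteins. The same latents drive CCI labels, PPI labels and DTA
#' affinities, which is what makes auxiliary pretraining transferable by
#' construction.
#'
#' @slot chemicals data.frame(id, smiles).
#' @slot proteins data.frame(id, sequence).
#' @slot chemLatents,protLatents numeric matrices, entities x latentDim.
#' @slot fragCounts,motifCounts raw structure-count matrices the latents
#'   were derived from.
#' @slot loadings list(fragment, motif) loading matrices.
#' @slot config the generating [syntheticWorldConfig()] list.
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  representation(
    chemicals   = "data.frame",
    proteins    = "data.frame",
    chemLatents = "matrix",
    protLatents = "matrix",
    fragCounts  = "matrix",
    motifCounts = "matrix",
    loadings    = "list",
    config      = "list"
  )
)

#' Transferable encoder parameters
#'
#' All trainable parameters of one drug or protein encoder together with the
#' configuration they were built under and a fingerprint of that
#' configuration. Checkpoints round-trip bit-exactly through
#' [saveEncoderState()] / [readEncoderState()], and [assembleDtaModel()]
#' refuses to load a state whose fingerprint disagrees with the model
#' configuration.
#'
#' @slot kind "gin" or "sequence".
#' @slot params named list of numeric arrays.
#' @slot config the encoder configuration list.
#' @slot fingerprint canonical string fingerprint of config.
#' @exportClass EncoderState
setClass("EncoderState",
  representation(
    kind        = "character",
    params      = "list",
    config      = "list",
    fingerprint = "character"
  )
)

setValidity("EncoderState", function(object) {
  if (!object@kind %in% c("gin", "sequence")) return("kind must be 'gin' or 'sequence'")
  if (object@fingerprint != configFingerprint(object@config))
    return("config fingerprint does not match config")
  TRUE
})

#' Drug-target affinity model
#'
#' A drug encoder, a protein encoder and a regression head. Encoders may be
#' freshly initialized or transferred from CCI/PPI pretraining checkpoints;
#' the head is always freshly initialized.
#'
#' @slot drugEncoder,proteinEncoder [EncoderState-class] objects.
#' @slot head named list of head parameters.
#' @slot headConfig the [pairHeadConfig()] list used for the head.
#' @slot info bookkeeping list (encoder provenance, training log).
#' @exportClass DtaModel
setClass("DtaModel",
  representation(
    drugEncoder    = "EncoderState",
    proteinEncoder = "EncoderState",
    head           = "list",
    headConfig     = "list",
    info           = "list"
  )
)

setMethod("show", "MoleculeGraph", function(object) {
  cat("MoleculeGraph:", object@smiles, "\n",
      " ", nrow(object@nodeFeatures), "heavy atoms,",
      sum(object@adjacency) / 2, "bonds,",
      ncol(object@nodeFeatures), "features/node\n")
})

setMethod("show", "PairDataset", function(object) {
  cat("PairDataset <", object@task, ">: ", nrow(object@pairs), " pairs, ",
      length(object@chemicals), " chemicals, ",
      length(object@proteins), " proteins\n", sep = "")
  if (object@task != "dta")
    cat("  label balance:", mean(object@pairs$label), "positive\n")
})

setMethod("show", "SplitManifest", function(object) {
  cat("SplitManifest <", object@regime, "> seed=", object@seed, "\n",
      "  train/valid/test records: ", length(object@train), "/",
      length(object@valid), "/", length(object@test), "\n", sep = "")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld:", nrow(object@chemicals), "chemicals,",
      nrow(object@proteins), "proteins, latent dim",
      ncol(object@chemLatents), "\n")
})

setMethod("show", "EncoderState", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat("EncoderState <", object@kind, ">: ", np, " parameters, fingerprint ",
      substr(object@fingerprint, 1, 40), "...\n", sep = "")
})

setMethod("show", "DtaModel", function(object) {
  cat("DtaModel\n  drug encoder:    ", object@drugEncoder@kind,
      " (", object@info$drugOrigin %||% "fresh", ")\n",
      "  protein encoder: ", object@proteinEncoder@kind,
      " (", object@info$proteinOrigin %||% "fresh", ")\n", sep = "")
})

# ---- accessors ----

#' Accessors for the core classes
#'
#' Small generics mirroring common Bioconductor accessor style: slot access
#' is never needed by user code.
#'
#' @param x object.
#' @return The corresponding component.
#' @name accessors
#' @aliases nodeFeatures adjacency pairRecords entityStore taskName
#'   splitIndices worldChemicals worldProteins worldLatents encoderParams
#'   encoderConfig
NULL

#' @rdname accessors
#' @export
nodeFeatures <- function(x) x@nodeFeatures

#' @rdname accessors
#' @export
adjacency <- function(x) x@adjacency

#' @rdname accessors
#' @export
pairRecords <- function(x) x@pairs

#' @rdname accessors
#' @param type "chemicals" or "proteins".
#' @export
entityStore <- function(x, type = c("chemicals", "proteins")) {
  type <- match.arg(type)
  slot(x, type)
}

#' @rdname accessors
#' @export
taskName <- function(x) x@task

#' @rdname accessors
#' @export
splitIndices <- function(x) list(train = x@train, valid = x@valid, test = x@test)

#' @rdname accessors
#' @export
worldChemicals <- function(x) x@chemicals

#' @rdname accessors
#' @export
worldProteins <- function(x) x@proteins

#' @rdname accessors
#' @param side "chemical" or "protein".
#' @export
worldLatents <- function(x, side = c("chemical", "protein")) {
  side <- match.arg(side)
  if (side == "chemical") x@chemLatents else x@protLatents
}

#' @rdname accessors
#' @export
encoderParams <- function(x) x@params

#' @rdname accessors
#' @export
encoderConfig <- function(x) x@config
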