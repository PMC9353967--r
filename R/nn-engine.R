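# Internal numeric engine: parameter initialization, batched forward and
# backward passes for the GIN graph encoder, the token-embedding sequence
# encoder and the pair heads, and the Adam optimizer. Parameters travel as
# flat named lists of numeric arrays; gradients mirror that structure, so the
# optimizer is a single loop over names. Row convention: samples are rows.

glorotMatrix <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -s, s), nin, nout)
}

ginInitParams <- function(cfg) {
  p <- list()
  cin <- cfg$nodeFeatureDim
  for (l in seq_len(cfg$numLayers)) {
    p[[paste0("L", l, ".W1")]] <- glorotMatrix(cin, cfg$hiddenDim)
    p[[paste0("L", l, ".b1")]] <- numeric(cfg$hiddenDim)
    p[[paste0("L", l, ".W2")]] <- glorotMatrix(cfg$hiddenDim, cfg$hiddenDim)
    p[[paste0("L", l, ".b2")]] <- numeric(cfg$hiddenDim)
    p[[paste0("L", l, ".eps")]] <- cfg$epsilonInit
    cin <- cfg$hiddenDim
  }
  p[["R.W0"]] <- glorotMatrix(cfg$hiddenDim, cfg$readoutHidden)
  p[["R.b0"]] <- numeric(cfg$readoutHidden)
  p[["R.W1"]] <- glorotMatrix(cfg$readoutHidden, cfg$outputDim)
  p[["R.b1"]] <- numeric(cfg$outputDim)
  p
}

seqInitParams <- function(cfg) {
  p <- list()
  if (isTRUE(cfg$providerTrainable))
    p[["E"]] <- matrix(rnorm(length(cfg$vocab) * cfg$embeddingDim, sd = 0.1),
                       length(cfg$vocab), cfg$embeddingDim)
  p[["P.W"]] <- glorotMatrix(cfg$embeddingDim, cfg$outputDim)
  p[["P.b"]] <- numeric(cfg$outputDim)
  p
}

headInitParams <- function(cfg) {
  if (isTRUE(cfg$literal)) {
    list("O.W" = glorotMatrix(2L * cfg$inputDim, 1L), "O.b" = numeric(1))
  } else {
    list("H.W" = glorotMatrix(2L * cfg$inputDim, cfg$hidden),
         "H.b" = numeric(cfg$hidden),
         "O.W" = glorotMatrix(cfg$hidden, 1L),
         "O.b" = numeric(1))
  }
}

# ---- graph batching ----

# Pack a list of MoleculeGraph objects into one block batch: stacked node
# features, a directed edge list (both directions of every bond, 0-based for
# the compiled kernels) and a graph id per node.
graphBatch <- function(graphs) {
  ns <- vapply(graphs, function(g) nrow(g@nodeFeatures), 1L)
  offs <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(graphs, nodeFeatures))
  el <- vector("list", length(graphs))
  for (k in seq_along(graphs)) {
    e <- which(graphs[[k]]@adjacency == 1, arr.ind = TRUE)
    if (nrow(e)) el[[k]] <- e + offs[k]
  }
  edges <- do.call(rbind, el)
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  groups <- lapply(seq_along(graphs), function(k) offs[k] + seq_len(ns[k]))
  list(X = X, ei = as.integer(edges[, 1] - 1L), ej = as.integer(edges[, 2] - 1L),
       gid = rep(seq_along(graphs), ns) - 1L, groups = groups,
       nGraphs = length(graphs), n = nrow(X))
}

ginParamStacks <- function(params, numLayers) {
  lget <- function(part) lapply(seq_len(numLayers), function(l)
    params[[paste0("L", l, ".", part)]])
  list(W1s = lget("W1"), b1s = lget("b1"), W2s = lget("W2"), b2s = lget("b2"),
       eps = vapply(seq_len(numLayers), function(l)
         params[[paste0("L", l, ".eps")]], 1))
}

poolMaxForward <- function(H, groups) {
  G <- length(groups)
  C <- ncol(H)
  P <- matrix(0, G, C)
  argmax <- matrix(0L, G, C)
  for (g in seq_len(G)) {
    rows <- groups[[g]]
    Hi <- H[rows, , drop = FALSE]
    am <- max.col(t(Hi), ties.method = "first") # argmax per column
    argmax[g, ] <- rows[am]
    P[g, ] <- Hi[cbind(am, seq_len(C))]
  }
  list(P = P, argmax = argmax)
}

ginForwardBatch <- function(params, batch, cfg, keepCache = FALSE) {
  st <- ginParamStacks(params, cfg$numLayers)
  res <- .ginForwardCpp(st$W1s, st$b1s, st$W2s, st$b2s, st$eps,
                        params[["R.W0"]], params[["R.b0"]],
                        params[["R.W1"]], params[["R.b1"]],
                        batch$X, batch$ei, batch$ej, batch$gid,
                        batch$nGraphs,
                        !identical(cfg$readoutActivation, "none"), keepCache)
  cache <- if (keepCache) list(ptr = res$cache, batch = batch, stacks = st)
  list(out = res$out, cache = cache)
}

ginBackwardBatch <- function(params, cache, dOut, cfg) {
  st <- cache$stacks
  gr <- .ginBackwardCpp(st$W1s, st$b1s, st$W2s, st$b2s, st$eps,
                        params[["R.W0"]], params[["R.W1"]], cache$ptr, dOut,
                        cache$batch$ei, cache$batch$ej,
                        !identical(cfg$readoutActivation, "none"))
  g <- list()
  for (l in seq_len(cfg$numLayers)) {
    g[[paste0("L", l, ".W1")]] <- gr$gW1s[[l]]
    g[[paste0("L", l, ".b1")]] <- drop(gr$gb1s[[l]])
    g[[paste0("L", l, ".W2")]] <- gr$gW2s[[l]]
    g[[paste0("L", l, ".b2")]] <- drop(gr$gb2s[[l]])
    g[[paste0("L", l, ".eps")]] <- gr$geps[[l]]
  }
  g[["R.W0"]] <- gr$gRW0
  g[["R.b0"]] <- drop(gr$gRb0)
  g[["R.W1"]] <- gr$gRW1
  g[["R.b1"]] <- drop(gr$gRb1)
  g
}

# ---- sequence encoder (composition form) ----

# For a lookup (non-contextual) provider, the mean over token embeddings
# equals normalizedTokenCounts %*% E; training uses that closed form.
seqForwardComp <- function(params, comp, cfg, keepCache = FALSE,
                           meanEmb = NULL) {
  M <- if (!is.null(params[["E"]])) as.matrix(comp %*% params[["E"]]) else meanEmb
  out <- addBias(M %*% params[["P.W"]], params[["P.b"]])
  list(out = out, cache = if (keepCache) list(M = M, comp = comp))
}

seqBackwardComp <- function(params, cache, dOut) {
  g <- list()
  g[["P.b"]] <- colSums(dOut)
  g[["P.W"]] <- crossprod(cache$M, dOut)
  if (!is.null(params[["E"]])) {
    dM <- tcrossprod(dOut, params[["P.W"]])
    g[["E"]] <- as.matrix(crossprod(cache$comp, dM))
  }
  g
}

# ---- pair heads ----

headForwardBatch <- function(params, J, cfg, keepCache = FALSE) {
  if (isTRUE(cfg$literal)) {
    Z <- addBias(J %*% params[["O.W"]], params[["O.b"]])
    out <- relu(Z)
    cache <- if (keepCache) list(J = J, Z = Z)
  } else {
    Zh <- addBias(J %*% params[["H.W"]], params[["H.b"]])
    Rh <- if (identical(cfg$activation, "none")) Zh else relu(Zh)
    out <- addBias(Rh %*% params[["O.W"]], params[["O.b"]])
    cache <- if (keepCache) list(J = J, Zh = Zh, Rh = Rh)
  }
  list(out = out, cache = cache)
}

headBackwardBatch <- function(params, cache, dOut, cfg) {
  g <- list()
  if (isTRUE(cfg$literal)) {
    dZ <- dOut * (cache$Z > 0)
    g[["O.b"]] <- colSums(dZ)
    g[["O.W"]] <- crossprod(cache$J, dZ)
    dJ <- tcrossprod(dZ, params[["O.W"]])
  } else {
    g[["O.b"]] <- colSums(dOut)
    g[["O.W"]] <- crossprod(cache$Rh, dOut)
    dRh <- tcrossprod(dOut, params[["O.W"]])
    dZh <- if (identical(cfg$activation, "none")) dRh else dRh * (cache$Zh > 0)
    g[["H.b"]] <- colSums(dZh)
    g[["H.W"]] <- crossprod(cache$J, dZh)
    dJ <- tcrossprod(dZh, params[["H.W"]])
  }
  list(grads = g, dJ = dJ)
}

# ---- Adam ----

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, skip = character()) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    if (nm %in% skip || is.null(grads[[nm]])) next
    gr <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gr
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

# prefix every name in a list (used to merge encoder + head parameter sets)
prefixNames <- function(x, pre) {
  names(x) <- paste0(pre, names(x))
  x
}

stripPrefix <- function(x, pre) {
  keep <- startsWith(names(x), pre)
  out <- x[keep]
  names(out) <- substring(names(out), nchar(pre) + 1L)
  out
}
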